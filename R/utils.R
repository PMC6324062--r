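# Geometry helpers shared across modules. The membrane normal is z;
# periodic boundaries are applied laterally (x, y) only.

# wrap displacements into the minimum image for one periodic edge
wrap_pbc <- function(d, edge) d - edge * round(d / edge)

# n x m matrix of distances between rows of a and rows of b,
# minimum-image in x/y, direct in z
mi_dist_matrix <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

# lateral (x,y) minimum-image distances between rows of a and rows of b
mi_lateral_dist_matrix <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dx <- dx - box[1] * round(dx / box[1])
  dy <- outer(a[, 2], b[, 2], "-")
  dy <- dy - box[2] * round(dy / box[2])
  sqrt(dx * dx + dy * dy)
}

# distance from each row of a to its nearest row in b (3D minimum image)
mi_nearest_dist <- function(a, b, box, chunk = 2048L) {
  n <- nrow(a)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1L)
    out[idx] <- apply(mi_dist_matrix(a[idx, , drop = FALSE], b, box), 1, min)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  if (is.null(class)) stop(msg, call. = FALSE)
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
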