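# Built-in progressive multiple sequence aligner: affine-gap (Gotoh)
# profile-profile dynamic programming with BLOSUM62 column scores and a
# neighbour-joining guide tree on pairwise identities. An external MSA
# tool (e.g. mafft) can be plugged in through a command adapter for
# fidelity at scale; the built-in route keeps the package self-contained.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# alignment rows (character matrix, rows = sequences) -> residue frequency
# profile: 20 x L matrix over amino-acid letters; gaps carry zero weight
profile_freq <- function(alnmat, letters = rownames(blosum62_matrix())[1:20]) {
  L <- ncol(alnmat)
  out <- matrix(0, nrow = length(letters), ncol = L,
                dimnames = list(letters, NULL))
  for (j in seq_len(L)) {
    col <- alnmat[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tb <- table(factor(col, levels = letters))
      out[, j] <- as.vector(tb) / nrow(alnmat)
    }
  }
  out
}

# profile-profile Gotoh alignment; returns merged alignment matrix
align_profiles <- function(A, B, gap_open = -10, gap_extend = -0.5) {
  S <- blosum62_matrix()[1:20, 1:20]
  fa <- profile_freq(A); fb <- profile_freq(B)
  la <- ncol(fa); lb <- ncol(fb)
  # column-column substitution scores: fa' S fb
  sub <- t(fa) %*% S %*% fb
  NEG <- -1e9
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)  # gap in B (consume A)
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in A (consume B)
  M[1, 1] <- 0
  X[2:(la + 1), 1] <- gap_open + gap_extend * (0:(la - 1))
  Y[1, 2:(lb + 1)] <- gap_open + gap_extend * (0:(lb - 1))
  ptrM <- matrix(0L, la + 1, lb + 1)
  ptrX <- matrix(0L, la + 1, lb + 1)
  ptrY <- matrix(0L, la + 1, lb + 1)
  for (i in 2:(la + 1)) {
    Mprev <- M[i - 1, ]; Xprev <- X[i - 1, ]; Yprev <- Y[i - 1, ]
    xo <- pmax(Mprev + gap_open, Xprev + gap_extend, Yprev + gap_open)
    X[i, ] <- xo
    ptrX[i, ] <- max.col(cbind(Mprev + gap_open, Xprev + gap_extend,
                               Yprev + gap_open), ties.method = "first")
    for (j in 2:(lb + 1)) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + sub[i - 1, j - 1]
      ptrM[i, j] <- k
      candy <- c(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                 Y[i, j - 1] + gap_extend)
      ky <- which.max(candy)
      Y[i, j] <- candy[ky]
      ptrY[i, j] <- ky
    }
  }
  # traceback
  i <- la + 1; j <- lb + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  pathA <- integer(); pathB <- integer()
  while (i > 1 || j > 1) {
    if (i == 1L) {
      pathA <- c(0L, pathA); pathB <- c(j - 1L, pathB); j <- j - 1L
    } else if (j == 1L) {
      pathA <- c(i - 1L, pathA); pathB <- c(0L, pathB); i <- i - 1L
    } else if (state == 1L) {
      pathA <- c(i - 1L, pathA); pathB <- c(j - 1L, pathB)
      state <- ptrM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      pathA <- c(i - 1L, pathA); pathB <- c(0L, pathB)
      state <- ptrX[i, j]; i <- i - 1L
    } else {
      pathA <- c(0L, pathA); pathB <- c(j - 1L, pathB)
      state <- ptrY[i, j]; j <- j - 1L
    }
  }
  L <- length(pathA)
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = L)
  out[seq_len(nrow(A)), pathA > 0L] <- A[, pathA[pathA > 0L], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), pathB > 0L] <-
    B[, pathB[pathB > 0L], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

pairwise_identity <- function(a, b) {
  m <- align_profiles(seq_to_mat(a, "a"), seq_to_mat(b, "b"))
  both <- m[1, ] != "-" & m[2, ] != "-"
  if (!any(both)) return(0)
  sum(m[1, both] == m[2, both]) / ncol(m)
}

seq_to_mat <- function(s, name) {
  matrix(strsplit(toupper(s), "")[[1]], nrow = 1,
         dimnames = list(name, NULL))
}

# post-order list of internal-node child sets from an NJ guide tree
guide_merge_order <- function(d, labels) {
  tr <- ape::nj(as.dist(d))
  tr <- ape::root(tr, outgroup = labels[1], resolve.root = TRUE)
  n <- length(labels)
  tips_under <- function(node) {
    if (node <= n) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  internal <- unique(tr$edge[, 1])
  # order internal nodes so children come before parents
  depth <- function(node) {
    if (node <= n) return(0L)
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    1L + max(vapply(kids, depth, integer(1)))
  }
  internal[order(vapply(internal, depth, integer(1)))]
  list(tree = tr, n_tips = n, tips_under = tips_under,
       internal = internal[order(vapply(internal, depth, integer(1)))])
}

#' Multiple sequence alignment of chain sequences
#'
#' Default aligner is the built-in progressive profile aligner (BLOSUM62,
#' gap open -10, gap extend -0.5, neighbour-joining guide tree on pairwise
#' identity). Pass `aligner = "mafft"` to delegate to an external mafft
#' executable, or supply a function `(named character vector) -> named
#' gapped character vector` as a custom adapter.
#'
#' @param sequences named character vector of amino-acid sequences (or a
#'   data.frame from [read_chain_sequences()], using `chain_id` as names).
#' @param aligner `"builtin"`, `"mafft"`, or a function.
#' @return object of class `cg_alignment`: named character vector of
#'   equal-length gapped sequences.
#' @export
align_members <- function(sequences, aligner = "builtin") {
  if (is.data.frame(sequences))
    sequences <- setNames(sequences$sequence, sequences$chain_id)
  if (length(sequences) < 2) stopf("alignment needs at least 2 sequences")
  if (any(!nzchar(sequences) | is.na(sequences)))
    stopf("empty sequence in alignment input")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (is.function(aligner)) {
    out <- aligner(sequences)
  } else if (identical(aligner, "mafft")) {
    out <- run_mafft(sequences)
  } else {
    out <- align_builtin(sequences)
  }
  stopifnot(length(unique(nchar(out))) == 1)
  structure(out[names(sequences)], class = "cg_alignment")
}

align_builtin <- function(sequences) {
  nm <- names(sequences)
  if (length(sequences) == 2) {
    m <- align_profiles(seq_to_mat(sequences[1], nm[1]),
                        seq_to_mat(sequences[2], nm[2]))
    return(setNames(apply(m, 1, paste, collapse = ""), nm))
  }
  n <- length(sequences)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - pairwise_identity(sequences[i], sequences[j])
  }
  g <- guide_merge_order(d, nm)
  profiles <- lapply(nm, function(x) seq_to_mat(sequences[x], x))
  names(profiles) <- nm
  done <- setNames(vector("list", length(nm)), nm)
  aln_of <- function(tipset) {
    if (length(tipset) == 1) return(profiles[[tipset]])
    key <- paste(sort(tipset), collapse = "|")
    done[[key]]
  }
  for (node in g$internal) {
    kids <- g$tree$edge[g$tree$edge[, 1] == node, 2]
    sub <- lapply(kids, function(k) {
      ts <- g$tips_under(k)
      aln_of(ts)
    })
    merged <- sub[[1]]
    if (length(sub) > 1)
      for (k in 2:length(sub)) merged <- align_profiles(merged, sub[[k]])
    key <- paste(sort(g$tips_under(node)), collapse = "|")
    done[[key]] <- merged
  }
  final <- done[[paste(sort(nm), collapse = "|")]]
  setNames(apply(final, 1, paste, collapse = ""), rownames(final))
}

run_mafft <- function(sequences) {
  if (Sys.which("mafft") == "")
    stopf("mafft executable not found on PATH")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences))), fin)
  status <- system2("mafft", c("--auto", "--quiet", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stopf("mafft failed with status %d", status)
  aa <- Biostrings::readAAStringSet(fout)
  setNames(toupper(as.character(aa)), sub("\\s.*$", "", names(aa)))
}

#' @export
print.cg_alignment <- function(x, ...) {
  cat(sprintf("<cg_alignment> %d sequences, %d columns\n",
              length(x), nchar(x[1])))
  for (i in seq_along(x))
    cat(sprintf("%-12s %s\n", names(x)[i],
                if (nchar(x[i]) > 60) paste0(substr(x[i], 1, 57), "...")
                else x[i]))
  invisible(x)
}

#' Write a gapped alignment to FASTA
#' @param alignment a `cg_alignment`.
#' @param path output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  writeLines(as.vector(rbind(paste0(">", names(alignment)),
                             unname(alignment))), path)
  invisible(path)
}
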