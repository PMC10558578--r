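#' Construct an LD matrix object
#'
#' Holds squared correlations (r^2) between SNPs. Values must lie in
#' `[0, 1]`, the matrix must be symmetric with a unit diagonal.
#'
#' @param r2 Square numeric matrix with rsid dimnames.
#' @param pos Optional named vector of base-pair positions (1-based).
#' @param tol Symmetry tolerance.
#' @return An object of class `ld_matrix`: list with `rsids`, `r2`, `pos`.
#' @export
ld_matrix <- function(r2, pos = NULL, tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) abort("LD matrix must be square.")
  if (is.null(rownames(r2)) && is.null(colnames(r2))) {
    abort("LD matrix needs rsid dimnames.")
  }
  rsids <- rownames(r2) %||% colnames(r2)
  dimnames(r2) <- list(rsids, rsids)
  if (any(r2 < -tol | r2 > 1 + tol)) abort("LD r^2 values must be in [0, 1].")
  if (max(abs(r2 - t(r2))) > tol) abort("LD matrix must be symmetric.")
  if (max(abs(diag(r2) - 1)) > tol) abort("LD matrix diagonal must be 1.")
  r2 <- pmin(pmax((r2 + t(r2)) / 2, 0), 1)
  diag(r2) <- 1
  if (!is.null(pos)) {
    if (is.null(names(pos))) names(pos) <- rsids
    pos <- pos[rsids]
  }
  structure(list(rsids = rsids, r2 = r2, pos = pos), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("<ld_matrix> ", length(x$rsids), " SNPs\n", sep = "")
  invisible(x)
}

#' Look up pairwise r^2
#'
#' @param ld `ld_matrix` object.
#' @param a,b rsid vectors (recycled).
#' @return Numeric vector of r^2; `NA` where a SNP is absent.
#' @export
ld_r2 <- function(ld, a, b) {
  out <- rep(NA_real_, max(length(a), length(b)))
  a <- rep_len(a, length(out)); b <- rep_len(b, length(out))
  ok <- a %in% ld$rsids & b %in% ld$rsids
  out[ok] <- ld$r2[cbind(a[ok], b[ok])]
  out
}

#' Read an LD matrix from text
#'
#' Accepts either a square TSV whose first column and header are rsids, or a
#' long three-column table `(rsid1, rsid2, r2)` (unlisted pairs default to 0).
#'
#' @param path File path.
#' @param pos Optional named base-pair positions.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, pos = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) == 3L && is.character(raw[[1]]) && is.character(raw[[2]]) &&
      is.numeric(raw[[3]])) {
    rsids <- sort(unique(c(raw[[1]], raw[[2]])))
    m <- matrix(0, length(rsids), length(rsids),
                dimnames = list(rsids, rsids))
    m[cbind(raw[[1]], raw[[2]])] <- raw[[3]]
    m[cbind(raw[[2]], raw[[1]])] <- raw[[3]]
    diag(m) <- 1
    return(ld_matrix(m, pos = pos))
  }
  rsids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1])
  rownames(m) <- rsids
  ld_matrix(m, pos = pos)
}

#' Simulate a block-diagonal LD matrix
#'
#' Fixture generator: SNPs are grouped into consecutive blocks with a common
#' within-block r^2 and zero r^2 across blocks.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param r2_within Within-block r^2, recycled across blocks.
#' @param rsids Optional rsid labels (default `snp1..snpK`).
#' @param spacing_bp Base-pair gap between adjacent SNPs in a block.
#' @param block_gap_bp Gap between blocks (default well beyond typical
#'   clumping windows).
#' @return An `ld_matrix` with positions.
#' @export
simulate_ld <- function(block_sizes, r2_within = 0.9, rsids = NULL,
                        spacing_bp = 10e3, block_gap_bp = 1e6) {
  k <- sum(block_sizes)
  r2_within <- rep_len(r2_within, length(block_sizes))
  if (any(r2_within < 0 | r2_within > 1)) {
    abort("`r2_within` must be in [0, 1].")
  }
  rsids <- rsids %||% paste0("snp", seq_len(k))
  if (length(rsids) != k) abort("`rsids` length must equal sum(block_sizes).")
  m <- matrix(0, k, k, dimnames = list(rsids, rsids))
  pos <- numeric(k)
  idx <- 0L; base <- 1e6
  for (b in seq_along(block_sizes)) {
    sel <- idx + seq_len(block_sizes[b])
    m[sel, sel] <- r2_within[b]
    pos[sel] <- base + (seq_along(sel) - 1) * spacing_bp
    base <- base + block_sizes[b] * spacing_bp + block_gap_bp
    idx <- idx + block_sizes[b]
  }
  diag(m) <- 1
  ld_matrix(m, pos = setNames(pos, rsids))
}
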