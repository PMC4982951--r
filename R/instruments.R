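#' LD pruning of a genotype dosage matrix
#'
#' Greedy left-to-right scan in SNP order: a SNP is dropped when its squared
#' Pearson correlation (on the dosage scale, pairwise-complete observations)
#' with an already-retained SNP inside the scan window exceeds the
#' threshold, so every removed SNP has a retained proxy with `r^2` above the
#' threshold and retained SNPs within a window are pairwise below it.
#' Monomorphic SNPs and SNPs with call rate below `min_call_rate` are
#' dropped with a warning before scanning.
#'
#' @param genotypes samples x SNPs dosage matrix (0/1/2, `NA` allowed).
#' @param r2_threshold squared-correlation threshold in (0, 1]; default 0.80.
#' @param window number of preceding retained SNPs compared against;
#'   default 100.
#' @param min_call_rate minimum per-SNP fraction of non-missing calls.
#' @return the genotype matrix restricted to retained SNPs, original order
#'   preserved; dropped SNP IDs in attribute `dropped`.
#' @export
ld_prune <- function(genotypes, r2_threshold = 0.80, window = 100L,
                     min_call_rate = 0.95) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 2L,
            r2_threshold > 0, r2_threshold <= 1)
  snp_ids <- colnames(genotypes) %||% as.character(seq_len(ncol(genotypes)))
  call_rate <- colMeans(!is.na(genotypes))
  low <- call_rate < min_call_rate
  vv <- apply(genotypes, 2L, stats::var, na.rm = TRUE)
  mono <- !low & (is.na(vv) | vv == 0)
  if (any(low))
    warning(sum(low), " SNP(s) dropped for call rate < ", min_call_rate)
  if (any(mono))
    warning(sum(mono), " monomorphic SNP(s) dropped")
  usable <- which(!low & !mono)
  kept <- integer(0)
  for (j in usable) {
    recent <- utils::tail(kept, window)
    prune <- FALSE
    if (length(recent)) {
      r <- suppressWarnings(
        stats::cor(genotypes[, j], genotypes[, recent, drop = FALSE],
                   use = "pairwise.complete.obs"))
      prune <- any(r^2 > r2_threshold, na.rm = TRUE)
    }
    if (!prune) kept <- c(kept, j)
  }
  out <- genotypes[, kept, drop = FALSE]
  attr(out, "dropped") <- setdiff(snp_ids, snp_ids[kept])
  out
}

#' Principal-component instruments from genome-wide genotypes
#'
#' Standardizes each SNP column (zero-variance columns dropped with a
#' warning) and extracts the top `k` principal components. These genome-wide
#' PCs summarize variation across many loci and serve as strong instrumental
#' variables for the trait network; this decomposition is distinct from the
#' PCA used for population-stratification correction. The sign of each
#' component is fixed deterministically: the loading with the largest
#' absolute value is made positive.
#'
#' @param genotypes samples x SNPs dosage matrix (complete cases only;
#'   impute or drop missing dosages first).
#' @param k number of components, at most `min(n samples, n SNPs)`.
#' @return an object of class `instrument_set`: list with `scores`
#'   (samples x k), `loadings`, `explained` (fraction of variance per PC,
#'   non-increasing), `pc_ids`, and empty `selected`/`associations` slots
#'   filled by [select_instruments()].
#' @export
compute_pcs <- function(genotypes, k = 50L) {
  stopifnot(is.matrix(genotypes))
  if (anyNA(genotypes))
    stop("compute_pcs requires complete dosages; impute or drop missing calls")
  vv <- apply(genotypes, 2L, stats::var)
  if (any(vv == 0)) {
    warning(sum(vv == 0), " zero-variance SNP(s) excluded from the PCA")
    genotypes <- genotypes[, vv > 0, drop = FALSE]
  }
  bound <- min(nrow(genotypes), ncol(genotypes))
  if (k > bound)
    stop("k = ", k, " exceeds min(n samples, n SNPs) = ", bound)
  pr <- stats::prcomp(genotypes, center = TRUE, scale. = TRUE, rank. = k)
  # deterministic sign: largest-magnitude loading of each PC is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  pc_ids <- sprintf("PC%d", seq_len(k))
  colnames(pr$x) <- colnames(pr$rotation) <- pc_ids
  rownames(pr$x) <- rownames(genotypes)
  structure(list(scores = pr$x,
                 loadings = pr$rotation,
                 explained = pr$sdev[seq_len(k)]^2 / sum(pr$sdev^2),
                 pc_ids = pc_ids,
                 selected = NULL,
                 associations = NULL),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", length(x$pc_ids), "genome-wide PCs on",
      nrow(x$scores), "samples\n")
  if (!is.null(x$selected))
    cat("  selected (backward elimination):",
        if (length(x$selected)) paste(x$selected, collapse = ", ") else "none",
        "\n")
  invisible(x)
}

#' Select significant principal-component instruments
#'
#' For each trait, regresses the trait on all candidate PCs and removes the
#' least significant PC until every remaining PC has `p <` `alpha` (backward
#' elimination). A PC is selected when it survives for at least one trait;
#' the per-PC associated traits, effect sizes and p-values are recorded.
#'
#' @param pcs an `instrument_set` from [compute_pcs()].
#' @param traits samples x traits numeric matrix, same sample order as the
#'   PC scores.
#' @param alpha significance level; default 0.001.
#' @return the `instrument_set` with `selected` (character vector of PC ids,
#'   in PC order) and `associations` (`data.frame` pc/trait/beta/p of the
#'   surviving terms) filled in.
#' @export
select_instruments <- function(pcs, traits, alpha = 0.001) {
  stopifnot(inherits(pcs, "instrument_set"))
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(pcs$scores))
    stop("sample mismatch: ", nrow(pcs$scores), " PC score rows vs ",
         nrow(traits), " trait rows")
  if (!is.null(rownames(traits)) && !is.null(rownames(pcs$scores)) &&
      !identical(rownames(traits), rownames(pcs$scores)))
    stop("sample IDs of PC scores and traits disagree; align rows first")
  stopifnot(alpha > 0, alpha <= 1)
  X <- pcs$scores
  assoc <- NULL
  for (tr in colnames(traits) %||% sprintf("T%d", seq_len(ncol(traits)))) {
    y <- traits[, tr]
    keep <- colnames(X)
    repeat {
      if (!length(keep)) break
      fit <- stats::lm(y ~ X[, keep, drop = FALSE])
      sm <- summary(fit)$coefficients
      pv <- sm[-1L, 4L]  # drop intercept
      names(pv) <- keep
      worst <- which.max(pv)
      if (pv[worst] >= alpha) keep <- keep[-worst] else break
    }
    if (length(keep)) {
      fit <- stats::lm(y ~ X[, keep, drop = FALSE])
      sm <- summary(fit)$coefficients
      assoc <- rbind(assoc, data.frame(pc = keep, trait = tr,
                                       beta = unname(sm[-1L, 1L]),
                                       p = unname(sm[-1L, 4L]),
                                       stringsAsFactors = FALSE))
    }
  }
  pcs$associations <- assoc %||%
    data.frame(pc = character(), trait = character(),
               beta = numeric(), p = numeric(), stringsAsFactors = FALSE)
  pcs$selected <- pcs$pc_ids[pcs$pc_ids %in% unique(pcs$associations$pc)]
  pcs
}
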