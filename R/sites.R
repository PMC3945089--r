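# PWM scanning: annotate candidate TF binding sites, plus the
# site-relocation negative control.

BASES <- c("A", "C", "G", "T")

seq_to_idx <- function(residues) {
  match(strsplit(residues, "")[[1]], BASES)  # N -> NA
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# per-position log(p/bg) matrix, motif length x 4
llr_matrix <- function(pwm) {
  log(sweep(pwm$probs, 2, pwm$background, "/"))
}

#' Log-likelihood-ratio score of a k-mer against a motif
#'
#' The score is the summed natural log of motif-over-background
#' probability per position.  On the minus strand the reverse complement
#' of the k-mer is scored.
#'
#' @param pwm A [pwm()] object.
#' @param kmer Character string of the motif's length over A, C, G, T.
#' @param strand `"+"` or `"-"`.
#' @return The LLR in nats.
#' @export
llr_score <- function(pwm, kmer, strand = "+") {
  kmer <- toupper(kmer)
  if (nchar(kmer) != nrow(pwm$probs))
    stop("k-mer length ", nchar(kmer), " does not match motif length ",
         nrow(pwm$probs))
  if (strand == "-") kmer <- revcomp(kmer)
  idx <- seq_to_idx(kmer)
  if (anyNA(idx)) stop("k-mer contains non-ACGT characters")
  lm <- llr_matrix(pwm)
  sum(lm[cbind(seq_len(nrow(lm)), idx)])
}

# maximum attainable LLR of the motif (consensus score)
llr_max <- function(pwm) sum(apply(llr_matrix(pwm), 1, max))

#' Scan a sequence for TF binding sites
#'
#' Both strands are scanned at every position; a site is kept iff its
#' relative affinity `exp(llr - llr_max)` meets the threshold.  At one
#' (position, TF) only the better-scoring strand is kept.  Windows
#' containing N are skipped.
#'
#' @param seq A [dna_sequence()].
#' @param pwms List of [pwm()] objects (their order defines `tf_index`).
#' @param rel_affinity_threshold Minimum relative affinity in `(0, 1]`.
#' @return An object of class `site_annotation`: list with `sequence_id`,
#'   `sites` (data frame: tf, tf_index, start, length, strand, llr,
#'   rel_affinity, sorted by start then strand) and `llr_max` (named
#'   per-TF consensus scores).
#' @export
scan_sites <- function(seq, pwms, rel_affinity_threshold = 0.01) {
  stopifnot(inherits(seq, "dna_sequence"))
  if (rel_affinity_threshold <= 0 || rel_affinity_threshold > 1)
    stop("threshold must be in (0, 1]")
  idx <- seq_to_idx(seq$residues)
  n <- length(idx)
  out <- list()
  lmax <- numeric(length(pwms))
  names(lmax) <- vapply(pwms, function(p) p$tf_name, "")
  for (t in seq_along(pwms)) {
    p <- pwms[[t]]
    L <- nrow(p$probs)
    lmax[t] <- llr_max(p)
    if (L > n) {
      warning("motif '", p$tf_name, "' longer than sequence '",
              seq$id, "'; no sites scanned")
      next
    }
    lm <- llr_matrix(p)
    # minus strand = plus-strand scan with the reverse-complemented motif
    lmrc <- lm[L:1, 4:1, drop = FALSE]
    np <- n - L + 1L
    fwd <- rev <- numeric(np)
    for (k in seq_len(L)) {
      b <- idx[k:(k + np - 1L)]
      fwd <- fwd + lm[k, ][b]
      rev <- rev + lmrc[k, ][b]
    }
    ok <- !is.na(fwd)  # windows containing N unscored
    if (any(!ok))
      message("sequence '", seq$id, "': windows containing N skipped for ",
              p$tf_name)
    thr <- lmax[t] + log(rel_affinity_threshold)
    use_fwd <- ok & fwd >= thr & fwd >= rev
    use_rev <- ok & rev >= thr & rev > fwd
    pos <- c(which(use_fwd), which(use_rev))
    if (!length(pos)) next
    llr <- c(fwd[use_fwd], rev[use_rev])
    out[[length(out) + 1L]] <- data.frame(
      tf = p$tf_name, tf_index = t, start = pos - 1L, length = L,
      strand = rep(c("+", "-"), c(sum(use_fwd), sum(use_rev))),
      llr = llr, rel_affinity = pmin(exp(llr - lmax[t]), 1))
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(), tf_index = integer(), start = integer(),
               length = integer(), strand = character(), llr = numeric(),
               rel_affinity = numeric())
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sequence_id = seq$id, sites = sites, llr_max = lmax),
            class = "site_annotation")
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf("<site_annotation> %s: %d sites, %d TFs\n", x$sequence_id,
              nrow(x$sites), length(x$llr_max)))
  invisible(x)
}

#' Relocate annotated sites to random positions (negative control)
#'
#' The multiset of sites (TF, score, affinity, length, strand) is
#' preserved; start positions are redrawn uniformly, avoiding exact
#' same-TF position duplicates.
#'
#' @param annotation A `site_annotation`.
#' @param seq_length Length of the sequence the sites live on (bp).
#' @param rng_seed Integer seed; the same seed reproduces the same
#'   relocation.
#' @return A new `site_annotation` with shuffled positions, sorted.
#' @export
shuffle_site_positions <- function(annotation, seq_length, rng_seed) {
  stopifnot(inherits(annotation, "site_annotation"))
  sites <- annotation$sites
  if (nrow(sites) && seq_length < max(sites$length))
    stop("sequence shorter than the longest site")
  set.seed(rng_seed)
  new_start <- integer(nrow(sites))
  for (t in unique(sites$tf_index)) {
    sel <- which(sites$tf_index == t)
    npos <- seq_length - sites$length[sel][1] + 1L
    if (length(sel) > npos)
      stop("more sites than available positions for TF index ", t)
    # sample without replacement within TF: no same-TF exact duplicates
    new_start[sel] <- sample.int(npos, length(sel), replace = FALSE) - 1L
  }
  sites$start <- new_start
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sequence_id = paste0(annotation$sequence_id, "_shuffled"),
                 sites = sites, llr_max = annotation$llr_max),
            class = "site_annotation")
}
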