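# Readers/writers and the shared spatial-axis data model.
#
# Conventions used throughout the package:
#   * sequence coordinates are 0-based, half-open (BED-compatible);
#   * the spatial axis is a fraction in [0, 1] of the anterior-posterior
#     (or any one-dimensional) body axis;
#   * expression and concentration values are unitless relative levels.

#' Construct a DNA sequence record
#'
#' @param id Sequence identifier.
#' @param residues Character string over the alphabet A, C, G, T, N
#'   (lowercase accepted, mapped to uppercase).
#' @return An object of class `dna_sequence` with elements `id` and
#'   `residues`.
#' @export
dna_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("sequence '", id, "' is empty")
  bad <- gsub("[ACGTN]", "", residues)
  if (nchar(bad) > 0L)
    stop("sequence '", id, "' contains illegal characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  structure(list(id = id, residues = residues), class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  cat(sprintf("<dna_sequence> %s (%d bp)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A list of [dna_sequence()] records, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  lapply(seq_along(set), function(i) {
    # first token of the header line is the id
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    dna_sequence(id, as.character(set[[i]]))
  })
}

#' Construct a position weight matrix
#'
#' Rows are motif positions, columns are A, C, G, T.  Counts (or
#' frequencies) are normalised row-wise to probabilities after adding a
#' pseudocount.
#'
#' @param counts Numeric matrix of non-negative counts, 4 columns.
#' @param tf_name Name of the transcription factor.
#' @param pseudocount Value added to every count before normalisation.
#' @param background Background nucleotide probabilities (length 4, sums
#'   to 1); defaults to uniform.
#' @return An object of class `pwm` with elements `tf_name`, `probs`
#'   (length x 4 probability matrix) and `background`.
#' @export
pwm <- function(counts, tf_name = "TF", pseudocount = 0.5,
                background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("PWM must have 4 columns (A, C, G, T); got ", ncol(counts))
  if (any(counts < 0)) stop("PWM counts must be non-negative")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9 ||
      any(background <= 0))
    stop("background must be 4 positive probabilities summing to 1")
  counts <- counts + pseudocount
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("PWM row of all zeros with zero pseudocount")
  probs <- counts / rs
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, probs = unname(probs) ,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, length %d\n", x$tf_name, nrow(x$probs)))
  invisible(x)
}

#' Read a PWM from a plain-text count matrix
#'
#' The file holds one motif: an optional `>name` header line followed by
#' one row per motif position with 4 whitespace-separated non-negative
#' numbers in A, C, G, T order.
#'
#' @inheritParams pwm
#' @param path Path to the matrix file.
#' @return A [pwm()] object.
#' @export
read_pwm <- function(path, pseudocount = 0.5, background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  tf_name <- sub("^\\.[a-z]+$", "", basename(path))
  if (length(lines) && startsWith(lines[1], ">")) {
    tf_name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (!length(lines)) stop("PWM file has no matrix rows: ", path)
  rows <- lapply(lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
    if (anyNA(v)) stop("non-numeric entry in PWM file: ", path)
    v
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L || ncols != 4L)
    stop("PWM file must have exactly 4 columns per row: ", path)
  pwm(do.call(rbind, rows), tf_name = tf_name, pseudocount = pseudocount,
      background = background)
}

#' Construct a spatial axis profile
#'
#' @param values Non-negative relative levels, one per axis bin.
#' @param axis Strictly increasing axis coordinates in `[0, 1]`; defaults
#'   to a uniform grid over `[0, 1]`.
#' @return An object of class `axis_profile` with elements `values` and
#'   `axis`.
#' @export
axis_profile <- function(values, axis = NULL) {
  values <- as.numeric(values)
  if (is.null(axis)) axis <- seq(0, 1, length.out = length(values))
  axis <- as.numeric(axis)
  if (length(values) != length(axis))
    stop("values and axis must have equal length")
  if (length(values) == 0L) stop("empty profile")
  if (any(values < 0)) stop("profile values must be non-negative")
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  if (axis[1] < 0 || axis[length(axis)] > 1)
    stop("axis coordinates must lie in [0, 1]")
  structure(list(values = values, axis = axis), class = "axis_profile")
}

#' @export
print.axis_profile <- function(x, ...) {
  cat(sprintf("<axis_profile> %d bins on [%.3g, %.3g], range [%.3g, %.3g]\n",
              length(x$values), x$axis[1], x$axis[length(x$axis)],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a trans-regulatory context
#'
#' Bundles the spatial concentration profiles and the fixed regulatory
#' roles of the transcription factors, all on one shared axis grid.
#'
#' @param conc Numeric matrix of relative TF concentrations, one column
#'   per TF (column names are TF names), one row per axis bin.
#' @param roles Character vector, `"activator"` or `"repressor"` per TF.
#' @param axis Axis coordinates; defaults to a uniform grid on `[0, 1]`.
#' @return An object of class `tf_context` with elements `tf_names`,
#'   `conc`, `roles`, `axis`.
#' @export
tf_context <- function(conc, roles, axis = NULL) {
  conc <- as.matrix(conc)
  if (is.null(colnames(conc))) stop("conc must have TF names as colnames")
  tf_names <- colnames(conc)
  if (any(conc < 0)) stop("concentrations must be non-negative")
  roles <- match.arg(roles, c("activator", "repressor"), several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, length(tf_names))
  if (length(roles) != length(tf_names))
    stop("one role per TF required")
  names(roles) <- tf_names
  if (is.null(axis)) axis <- seq(0, 1, length.out = nrow(conc))
  if (length(axis) != nrow(conc)) stop("axis length must match conc rows")
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  structure(list(tf_names = tf_names, conc = conc, roles = roles,
                 axis = as.numeric(axis)),
            class = "tf_context")
}

#' @export
print.tf_context <- function(x, ...) {
  cat(sprintf("<tf_context> %d TFs on %d axis bins\n",
              length(x$tf_names), length(x$axis)))
  cat(" ", paste(sprintf("%s(%s)", x$tf_names,
                         substr(x$roles, 1, 1)), collapse = " "), "\n")
  invisible(x)
}

#' Read spatial profiles from a TSV table
#'
#' First column: axis position in `[0, 1]` (or `[0, 100]` percent, which
#' is rescaled); remaining columns: one profile per column.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param roles Optional per-TF roles; if supplied, a [tf_context()] is
#'   returned, otherwise a single [axis_profile()] (one value column) or
#'   a list of profiles.
#' @return An `axis_profile`, list of profiles, or `tf_context`.
#' @export
read_profile_table <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(tab) < 2L) stop("profile table needs an axis and a value column")
  ax <- as.numeric(tab[[1]])
  if (anyNA(ax)) stop("non-numeric axis column")
  if (any(duplicated(ax))) stop("duplicated axis position in ", path)
  if (any(diff(ax) <= 0)) stop("axis column must be strictly increasing")
  if (max(ax) > 1) ax <- ax / 100  # percent-of-axis convention
  if (min(ax) < 0 || max(ax) > 1) stop("axis positions outside [0, 100]")
  vals <- tab[-1]
  if (any(vals < 0, na.rm = TRUE)) stop("negative profile values in ", path)
  profs <- lapply(vals, function(v) axis_profile(as.numeric(v), ax))
  names(profs) <- names(vals)
  if (!is.null(roles)) {
    conc <- sapply(profs, function(p) p$values)
    colnames(conc) <- names(profs)
    return(tf_context(conc, roles, axis = ax))
  }
  if (length(profs) == 1L) profs[[1]] else profs
}

#' Resample a profile onto a new axis grid
#'
#' Linear interpolation; extrapolation outside the profile's axis range
#' is an error.  Values are clipped at 0.
#'
#' @param p An [axis_profile()].
#' @param target_axis Strictly increasing coordinates within the range of
#'   `p$axis`.
#' @return An [axis_profile()] on `target_axis`.
#' @export
resample_profile <- function(p, target_axis) {
  stopifnot(inherits(p, "axis_profile"))
  target_axis <- as.numeric(target_axis)
  if (min(target_axis) < min(p$axis) - 1e-12 ||
      max(target_axis) > max(p$axis) + 1e-12)
    stop("target axis extends beyond the profile's range (extrapolation)")
  v <- approx(p$axis, p$values, xout = target_axis, rule = 1)$y
  axis_profile(pmax(v, 0), target_axis)
}

#' Write selected windows to a BED6 file
#'
#' Scores are the window weights rescaled to `0..1000` relative to the
#' maximum weight.
#'
#' @param windows Data frame with columns `start` and `length`
#'   (locus-relative, 0-based half-open) and optionally `weight`.
#' @param path Output file path.
#' @param chrom Chromosome name for the BED records.
#' @param locus_start Genomic coordinate of locus position 0.
#' @return The path, invisibly.
#' @export
write_windows_bed <- function(windows, path, chrom = "locus",
                              locus_start = 0L) {
  header <- sprintf("# %d windows, chrom=%s, locus_start=%d",
                    NROW(windows), chrom, locus_start)
  if (NROW(windows) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (any(windows$start < 0)) stop("negative window coordinates")
  w <- if (!is.null(windows$weight)) windows$weight else rep(1, nrow(windows))
  score <- if (max(w) > 0) round(1000 * w / max(w)) else rep(0L, length(w))
  bed <- data.frame(chrom = chrom,
                    start = locus_start + windows$start,
                    end = locus_start + windows$start + windows$length,
                    name = sprintf("window_%d", seq_len(nrow(windows))),
                    score = score,
                    strand = ".")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
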