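#' Construct an aligned multiple-sequence profile
#'
#' @param seqs Named character vector of aligned amino-acid sequences
#'   (equal length, `-` for gaps), 2-3 taxa.
#' @return A list of class `msa_profile` with `taxa`, `seqs` (character
#'   matrix, taxa x columns) and `length`.
#' @export
msa_profile <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 2L) stop("need at least 2 taxa")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  structure(list(taxa = names(seqs), seqs = mat, length = lens[1L]),
            class = "msa_profile")
}

#' Read an aligned FASTA or Clustal file into an `msa_profile`
#'
#' @param path File path.
#' @param format `"fasta"` (default) or `"clustal"`.
#' @return An `msa_profile`.
#' @export
read_msa <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading alignments requires the Biostrings package")
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::AAStringSet(aln))
  msa_profile(seqs)
}

#' Pairwise amino-acid divergence of two aligned sequences
#'
#' The proportion of differing columns among columns where both
#' sequences have a residue; columns with a gap in either sequence are
#' excluded from numerator and denominator.
#'
#' @param seqA,seqB Aligned sequences (equal-length character strings).
#' @return A proportion in \[0, 1\].
#' @examples
#' pairwise_divergence("AAAA", "AAAT")  # 0.25
#' @export
pairwise_divergence <- function(seqA, seqB) {
  a <- strsplit(toupper(seqA), "")[[1L]]
  b <- strsplit(toupper(seqB), "")[[1L]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) stop("no comparable columns")
  mean(a[comparable] != b[comparable])
}

# alignment column -> ungapped 1-based position on a reference taxon
.ref_positions <- function(msa, ref) {
  refseq <- msa$seqs[ref, ]
  pos <- cumsum(refseq != "-")
  pos[refseq == "-"] <- NA_integer_
  pos
}

#' Lineage-specific amino-acid changes of a focal taxon
#'
#' A column carries a change unique to the focal taxon when the focal
#' residue differs while all other taxa agree on one residue. Columns
#' with a gap in any taxon are excluded from substitution calls.
#'
#' @param msa An `msa_profile` with at least 3 taxa.
#' @param focal The focal taxon name.
#' @param ref Reference taxon for ungapped coordinates (default: the
#'   first non-focal taxon).
#' @return A `data.frame`: `column` (alignment column), `ref_pos`
#'   (ungapped position on `ref`), `from` (residue shared by the other
#'   taxa), `to` (focal residue). Attribute `ref` records the reference
#'   taxon.
#' @export
lineage_specific_changes <- function(msa, focal, ref = NULL) {
  stopifnot(inherits(msa, "msa_profile"))
  if (!focal %in% msa$taxa) stop("focal taxon not in alignment: ", focal)
  if (length(msa$taxa) < 3L) stop("need a focal taxon plus at least 2 others")
  others <- setdiff(msa$taxa, focal)
  if (is.null(ref)) ref <- others[1L]
  stopifnot(ref %in% msa$taxa)
  s <- msa$seqs
  no_gap <- colSums(s == "-") == 0L
  others_agree <- apply(s[others, , drop = FALSE], 2L,
                        function(col) length(unique(col)) == 1L)
  focal_diff <- s[focal, ] != s[others[1L], ]
  hit <- which(no_gap & others_agree & focal_diff)
  refpos <- .ref_positions(msa, ref)
  out <- data.frame(column = hit, ref_pos = refpos[hit],
                    from = s[others[1L], hit], to = s[focal, hit],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ref") <- ref
  attr(out, "focal") <- focal
  out
}

#' Sliding-window divergence profile
#'
#' For each position along the sequence, the proportion of change
#' columns inside a centered window. Windows truncated at the sequence
#' ends use the truncated width as denominator.
#'
#' @param changes Integer vector of change positions (e.g. the `column`
#'   or `ref_pos` of [lineage_specific_changes()]).
#' @param length Sequence (or alignment) length the profile spans.
#' @param window Odd window width in residues (default 9).
#' @return A `data.frame`: `position`, `proportion` in \[0, 1\].
#' @export
window_divergence <- function(changes, length, window = 9L) {
  window <- as.integer(window)
  length <- as.integer(length)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > length) stop("window wider than the sequence")
  changes <- unique(as.integer(changes))
  if (any(changes < 1L | changes > length)) stop("change positions out of range")
  ind <- integer(length)
  ind[changes] <- 1L
  half <- (window - 1L) %/% 2L
  prop <- vapply(seq_len(length), function(i) {
    lo <- max(1L, i - half); hi <- min(length, i + half)
    sum(ind[lo:hi]) / (hi - lo + 1L)
  }, numeric(1))
  data.frame(position = seq_len(length), proportion = prop)
}

#' Default polar / nonpolar partition of the 20 amino acids
#' @return Named character vector mapping one-letter codes to
#'   `"polar"` or `"nonpolar"`.
#' @export
polarity_classes <- function() {
  polar <- c("R", "N", "D", "C", "Q", "E", "G", "H", "K", "S", "T", "Y")
  nonpolar <- c("A", "I", "L", "M", "F", "P", "W", "V")
  stats::setNames(c(rep("polar", length(polar)),
                    rep("nonpolar", length(nonpolar))),
                  c(polar, nonpolar))
}

#' Flag polarity-inverting substitutions
#'
#' A substitution inverts polarity when the ancestral and derived
#' residues fall on opposite sides of the polar/nonpolar partition.
#'
#' @param changes A `data.frame` with `from` and `to` residue columns
#'   (e.g. from [lineage_specific_changes()]).
#' @param classes Named polarity table (default [polarity_classes()]).
#' @return `changes` with added columns `polarity_inversion` (logical)
#'   and `direction` (`"gain"`: nonpolar to polar, `"loss"`: polar to
#'   nonpolar, `NA` otherwise).
#' @export
polarity_inversions <- function(changes, classes = polarity_classes()) {
  stopifnot(all(c("from", "to") %in% names(changes)))
  unknown <- setdiff(unique(c(changes$from, changes$to)), names(classes))
  if (length(unknown) > 0L)
    stop("unknown residue code: ", paste(unknown, collapse = ", "))
  cf <- classes[changes$from]
  ct <- classes[changes$to]
  changes$polarity_inversion <- unname(cf != ct)
  changes$direction <- ifelse(!changes$polarity_inversion, NA_character_,
                              ifelse(ct == "polar", "gain", "loss"))
  changes
}

#' Count changes falling inside named domains
#'
#' @param changes A `data.frame` with a `ref_pos` column of ungapped
#'   1-based positions on the reference sequence.
#' @param domains A `data.frame` with `name`, `start`, `end` (1-based
#'   inclusive, reference coordinates).
#' @return A `data.frame`: `name`, `start`, `end`, `n_changes`.
#' @export
domain_overlap <- function(changes, domains) {
  if (is.null(domains) || nrow(domains) == 0L)
    return(data.frame(name = character(), start = integer(),
                      end = integer(), n_changes = integer()))
  stopifnot(all(c("name", "start", "end") %in% names(domains)),
            "ref_pos" %in% names(changes))
  if (any(domains$start > domains$end)) stop("domain start after end")
  n <- vapply(seq_len(nrow(domains)), function(k) {
    sum(!is.na(changes$ref_pos) &
        changes$ref_pos >= domains$start[k] &
        changes$ref_pos <= domains$end[k])
  }, integer(1))
  data.frame(name = domains$name, start = domains$start, end = domains$end,
             n_changes = n, stringsAsFactors = FALSE)
}

#' Read a domain map from a TSV file
#'
#' Expects columns `name`, `start`, `end` (1-based inclusive, on the
#' ungapped reference sequence).
#' @param path File path.
#' @return A `data.frame` usable with [domain_overlap()].
#' @export
read_domains <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "start", "end") %in% names(d)))
  d
}

#' Detect insertion/deletion blocks in an alignment
#'
#' Maximal runs of alignment columns sharing the same gap pattern are
#' reported as one block each. With n taxa, a gap in n-1 taxa is an
#' insertion in the remaining lineage; a gap in exactly one taxon is a
#' deletion in that lineage; other patterns are reported as `complex`.
#'
#' @param msa An `msa_profile`.
#' @return A `data.frame`: `start`, `length`, `gap_taxa`
#'   (comma-separated), `event` (`insertion`, `deletion`, `complex`),
#'   `lineage` (the inserted/deleted lineage, `NA` for complex).
#' @export
indel_blocks <- function(msa) {
  stopifnot(inherits(msa, "msa_profile"))
  s <- msa$seqs
  n <- length(msa$taxa)
  pattern <- apply(s == "-", 2L, function(col) paste(which(col), collapse = ","))
  r <- rle(pattern)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  if (!any(keep))
    return(data.frame(start = integer(), length = integer(),
                      gap_taxa = character(), event = character(),
                      lineage = character(), stringsAsFactors = FALSE))
  out <- lapply(which(keep), function(k) {
    gi <- as.integer(strsplit(r$values[k], ",")[[1L]])
    event <- if (length(gi) == n) "all_gap"
             else if (n >= 3L && length(gi) == n - 1L) "insertion"
             else if (length(gi) == 1L && n >= 3L) "deletion"
             else "complex"
    lineage <- switch(event,
      insertion = msa$taxa[setdiff(seq_len(n), gi)],
      deletion = msa$taxa[gi],
      NA_character_)
    data.frame(start = starts[k], length = r$lengths[k],
               gap_taxa = paste(msa$taxa[gi], collapse = ","),
               event = event, lineage = lineage, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[res$event != "all_gap", ]
  rownames(res) <- NULL
  res
}
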