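# Full feature vectors: PseAAC difference block + full-length protein
# attributes + per-base evolutionary conservation scores.

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file (chrom, start, end, score; 0-based half-open).
#' @param name Track label, e.g. \code{"gerp"}, \code{"phylop"},
#'   \code{"siphy"}.
#' @return Object of class \code{cons_track} wrapping a \code{GRanges} with
#'   a \code{score} column.
#' @export
read_conservation_track <- function(path, name) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  new_cons_track(name, gr)
}

#' @rdname read_conservation_track
#' @param gr \code{GRanges} with a \code{score} column.
#' @export
new_cons_track <- function(name, gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr), score = gr$score)
  index <- lapply(split(df[c("start", "end", "score")], df$chrom),
                  function(d) d[order(d$start), ])
  structure(list(name = name, gr = gr, index = index),
            class = "cons_track")
}

# Scores of a track at 1-based genomic positions; NA where uncovered.
.track_scores <- function(track, chrom, positions) {
  idx <- track$index[[chrom]]
  if (is.null(idx)) return(rep(NA_real_, length(positions)))
  i <- findInterval(positions, idx$start)
  covered <- i > 0L & positions <= idx$end[pmax(i, 1L)]
  ifelse(covered, idx$score[pmax(i, 1L)], NA_real_)
}

#' Protein length difference and ratio
#'
#' @param cc A \code{coding_change}.
#' @return Named numeric vector \code{c(len_diff, len_ratio)}, mutant minus
#'   (or over) wild, so a net loss of residues is negative / below 1.
#' @export
length_features <- function(cc) {
  if (cc$protein_len_wild == 0L) stop("zero-length wild protein")
  c(len_diff = cc$protein_len_mut - cc$protein_len_wild,
    len_ratio = cc$protein_len_mut / cc$protein_len_wild)
}

#' Variant position normalized by protein length
#'
#' The index of the first changed residue divided by the wild protein
#' length: a change at residue 90 of a 100-residue protein scores 0.9.
#' For pure insertions the left flanking residue index is used, so the
#' value stays in [0, 1].
#'
#' @param cc A \code{coding_change}.
#' @return Numeric in [0, 1].
#' @export
position_feature <- function(cc) {
  if (cc$protein_len_wild == 0L) stop("zero-length wild protein")
  min(cc$first_changed_aa, cc$protein_len_wild) / cc$protein_len_wild
}

#' Conservation scores of a variant under the indel max policy
#'
#' SNVs (and multi-nucleotide substitutions) take the score at the
#' substituted base (the maximum over bases for MNVs); deletions the
#' maximum over the deleted bases; insertions the maximum over the two
#' flanking reference bases.  A track with no score at any queried base
#' contributes 0 and raises the \code{missing} flag.
#'
#' @param v Variant (list/one-row data.frame: chrom, pos, ref, alt).
#' @param tracks List of three \code{cons_track}s (gerp-, phylop-,
#'   siphy-like, in that order).
#' @return List with \code{scores} (named numeric length 3) and
#'   \code{missing} (logical: any track imputed).
#' @export
conservation_features <- function(v, tracks) {
  tr <- .trim_alleles(as.integer(v$pos), toupper(as.character(v$ref)),
                      toupper(as.character(v$alt)))
  nref <- nchar(tr$ref)
  positions <- if (nref > 0L) tr$pos + seq_len(nref) - 1L
               else c(tr$pos - 1L, tr$pos)
  out <- numeric(length(tracks))
  miss <- FALSE
  for (i in seq_along(tracks)) {
    s <- .track_scores(tracks[[i]], as.character(v$chrom), positions)
    if (all(is.na(s))) {
      out[i] <- 0
      miss <- TRUE
    } else out[i] <- max(s, na.rm = TRUE)
  }
  names(out) <- vapply(tracks, `[[`, "", "name")
  list(scores = out, missing = miss)
}

#' Column names of the numeric feature block
#'
#' @param lambda PseAAC tier count.
#' @return Character vector of length 20 + 2*lambda + 6.
#' @export
feature_names <- function(lambda) {
  c(sprintf("pseaac_d%02d", seq_len(20L + 2L * lambda)),
    "len_diff", "len_ratio", "norm_pos",
    "cons_gerp", "cons_phylop", "cons_siphy")
}

#' Assemble one complete feature vector
#'
#' Fixed column order: PseAAC difference, length difference, length ratio,
#' normalized position, then the three conservation scores.  Dimension is
#' 20 + 2*lambda + 6 (50 at lambda = 12).
#'
#' @param cc A \code{coding_change}.
#' @param pseaac_diff Numeric vector from \code{\link{pseaac_diff}}.
#' @param lenfeat From \code{\link{length_features}}.
#' @param posfeat From \code{\link{position_feature}}.
#' @param consfeat From \code{\link{conservation_features}}.
#' @param label Optional \code{"damaging"}/\code{"tolerated"}.
#' @return One-row data.frame: numeric features, \code{cons_missing} flag,
#'   \code{label}, \code{group_key} (chrom:pos:ref:alt) and
#'   \code{transcript_id}.
#' @export
assemble_features <- function(cc, pseaac_diff, lenfeat, posfeat, consfeat,
                              label = NA_character_) {
  lambda <- (length(pseaac_diff) - 20L) %/% 2L
  vals <- c(pseaac_diff, lenfeat[["len_diff"]], lenfeat[["len_ratio"]],
            posfeat, unname(consfeat$scores))
  nm <- feature_names(lambda)
  if (length(vals) != length(nm))
    stop("feature block dimension mismatch: got ", length(vals),
         ", expected ", length(nm))
  row <- as.data.frame(as.list(stats::setNames(vals, nm)))
  row$cons_missing <- consfeat$missing
  row$label <- label
  row$group_key <- paste(cc$chrom, cc$pos, cc$ref, cc$alt, sep = ":")
  row$transcript_id <- cc$transcript_id
  row
}

#' Encode a coding change as its feature vector
#'
#' Runs snippet extraction, PseAAC encoding of both snippets, the
#' wild-minus-mutant difference, the full-length attributes and the
#' conservation lookup.
#'
#' @param cc A \code{coding_change} (non-synonymous).
#' @param tracks List of three \code{cons_track}s, or \code{NULL} to emit
#'   zero conservation scores.
#' @param scales Normalized \code{aa_scales}.
#' @param lambda,w PseAAC parameters.
#' @param label Optional class label.
#' @return One-row feature data.frame (see \code{\link{assemble_features}}),
#'   or \code{NULL} with a \code{"short_sequence"} condition class if the
#'   mutant snippet is shorter than lambda + 1 (handled by the
#'   deleterious-by-rule shortcut).
#' @export
encode_variant <- function(cc, tracks = NULL, scales = normalize_scales(),
                           lambda = 12L, w = 0.1, label = NA_character_) {
  sn <- extract_snippets(cc)
  if (sn$mutant$L < lambda + 1L || sn$wild$L < lambda + 1L)
    stop(structure(class = c("short_sequence", "error", "condition"),
                   list(message = paste0("snippet of length ",
                                         min(sn$mutant$L, sn$wild$L),
                                         " shorter than lambda + 1 = ",
                                         lambda + 1L),
                        call = NULL, length = min(sn$mutant$L, sn$wild$L))))
  pw <- pseaac_vector(sn$wild$sequence, scales, lambda, w)
  pm <- pseaac_vector(sn$mutant$sequence, scales, lambda, w)
  d <- pseaac_diff(pw, pm)
  cons <- if (is.null(tracks))
    list(scores = c(gerp = 0, phylop = 0, siphy = 0), missing = TRUE)
  else conservation_features(cc, tracks)
  assemble_features(cc, d, length_features(cc), position_feature(cc),
                    cons, label)
}

#' Write / read a feature matrix as TSV
#'
#' @param features Feature data.frame.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
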