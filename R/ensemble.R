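# Standardization of external predictor scores around their decision
# thresholds and the three-way majority-voting ensemble.

#' Default decision thresholds of the external predictors
#'
#' PolyPhen2 calls damaging above 0.447 (damaging-high); SIFT calls
#' damaging below 0.05 (damaging-low).
#' @return Named list of (threshold, orientation) per tool.
#' @export
external_tool_defaults <- function()
  list(polyphen2 = list(threshold = 0.447, orientation = "damaging_high"),
       sift = list(threshold = 0.05, orientation = "damaging_low"))

#' Standardize an external predictor score around its threshold
#'
#' Piecewise-linear remap of a raw score in [0, 1]: after orienting so that
#' damaging is high, the tolerated side of the threshold is mapped onto
#' [0, 0.5) and the damaging side onto [0.5, 1], with endpoints fixed and
#' the threshold itself landing exactly on 0.5 (counted as damaging, like
#' the classifier's own 0.5).
#'
#' @param raw_score Raw tool score in [0, 1].
#' @param tool \code{"polyphen2"} or \code{"sift"} (sets threshold and
#'   orientation defaults).
#' @param threshold,orientation Override the tool defaults.
#' @return Standardized score in [0, 1]; damaging iff >= 0.5.
#' @examples
#' standardize_external(0.0, "sift")    # 1.0  (maximally damaging)
#' standardize_external(0.447, "polyphen2")  # 0.5
#' @export
standardize_external <- function(raw_score, tool = c("polyphen2", "sift"),
                                 threshold = NULL, orientation = NULL) {
  tool <- match.arg(tool)
  def <- external_tool_defaults()[[tool]]
  t <- if (is.null(threshold)) def$threshold else threshold
  o <- if (is.null(orientation)) def$orientation else orientation
  if (is.na(raw_score)) return(NA_real_)
  if (raw_score < 0 || raw_score > 1)
    stop("raw score ", raw_score, " outside [0, 1]")
  if (o == "damaging_low") raw_score <- 1 - raw_score
  td <- if (o == "damaging_low") 1 - t else t
  if (raw_score >= td) {
    if (td == 1) 1 else 0.5 + 0.5 * (raw_score - td) / (1 - td)
  } else {
    if (td == 0) 0 else 0.5 * raw_score / td
  }
}

#' Majority vote over classifier and external predictions
#'
#' With all three scores available the class is the majority class and the
#' reported score is the standardized score of the most confident tool
#' (largest distance from 0.5) among those voting with the majority, so
#' class and score never disagree.  With one external score missing, the
#' more confident of the two remaining tools sets both class and score.
#' With both missing, the classifier's prediction stands alone.
#'
#' @param rf Classifier prediction: data.frame/list with \code{class},
#'   \code{score} and optionally \code{source} (\code{"rule"} marks the
#'   short-sequence shortcut).
#' @param pp2_std,sift_std Standardized external scores in [0, 1], or
#'   \code{NA}/\code{NULL} when the tool gave no prediction.
#' @return One-row data.frame: \code{class}, \code{score},
#'   \code{decided_by} (majority3, confidence2, rf_only or rule),
#'   \code{rf_score}, \code{pp2_std}, \code{sift_std}.
#' @export
vote_ensemble <- function(rf, pp2_std = NA_real_, sift_std = NA_real_) {
  if (is.null(pp2_std)) pp2_std <- NA_real_
  if (is.null(sift_std)) sift_std <- NA_real_
  scores <- c(rf = as.numeric(rf$score), pp2 = pp2_std, sift = sift_std)
  avail <- !is.na(scores)
  classes <- ifelse(scores >= 0.5, "damaging", "tolerated")
  if (all(avail)) {
    maj <- if (sum(classes == "damaging") >= 2) "damaging" else "tolerated"
    side <- which(avail & classes == maj)
    final <- scores[side][which.max(abs(scores[side] - 0.5))]
    decided <- "majority3"
  } else if (sum(avail) == 2L) {
    side <- which(avail)
    pick <- side[which.max(abs(scores[side] - 0.5))]
    maj <- classes[pick]
    final <- scores[pick]
    decided <- "confidence2"
  } else {
    maj <- classes[["rf"]]
    final <- scores[["rf"]]
    decided <- if (!is.null(rf$source) && identical(rf$source[1], "rule"))
      "rule" else "rf_only"
  }
  data.frame(class = unname(maj), score = unname(final),
             decided_by = decided, rf_score = unname(scores[["rf"]]),
             pp2_std = pp2_std, sift_std = sift_std,
             stringsAsFactors = FALSE)
}

#' Read external predictor scores
#'
#' TSV keyed by chrom, pos, ref, alt (optionally transcript) with columns
#' \code{pp2_score} and \code{sift_score}; blank cells mean the tool gave
#' no prediction.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_external_scores <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

.lookup_external <- function(external, v, transcript_id) {
  if (is.null(external) || !nrow(external))
    return(c(pp2 = NA_real_, sift = NA_real_))
  hit <- external$chrom == as.character(v$chrom) &
    external$pos == as.integer(v$pos) &
    external$ref == as.character(v$ref) &
    external$alt == as.character(v$alt)
  if ("transcript" %in% names(external))
    hit <- hit & (is.na(external$transcript) |
                    external$transcript == transcript_id)
  i <- which(hit)
  if (!length(i)) return(c(pp2 = NA_real_, sift = NA_real_))
  c(pp2 = as.numeric(external$pp2_score[i[1]]),
    sift = as.numeric(external$sift_score[i[1]]))
}

#' Score variants end to end
#'
#' For every variant and every transcript whose CDS it hits: project the
#' variant onto the protein, apply the short-sequence deleterious rule or
#' encode the feature vector and score it with the fitted classifier, then
#' fold in any external PolyPhen2/SIFT scores through
#' \code{\link{vote_ensemble}}.  Synonymous, non-coding and unsupported
#' (> 60 nt, splice-spanning) variants are skipped with a reason.
#'
#' @param variants data.frame from \code{\link{read_variants}}.
#' @param transcripts List of \code{\link{transcript}} objects.
#' @param genome Named character vector of chromosome sequences.
#' @param model Fitted \code{\link{fit_classifier}} object.
#' @param tracks Optional list of three \code{cons_track}s.
#' @param external Optional external-score data.frame
#'   (\code{\link{read_external_scores}}).
#' @param scales Normalized amphiphilic scales.
#' @return data.frame with one row per scored transcript-variant
#'   (variant, transcript, gene, variant_class, final class/score, the
#'   per-tool scores, decided_by, conservation scores); skipped variants
#'   are recorded in \code{attr(, "skipped")}.
#' @export
score_variants <- function(variants, transcripts, genome, model,
                           tracks = NULL, external = NULL,
                           scales = normalize_scales()) {
  lambda <- model$params$lambda
  w <- model$params$w
  out <- list()
  skipped <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    for (tx in transcripts) {
      cc <- apply_variant(tx, genome, v)
      if (inherits(cc, "not_coding")) next
      if (inherits(cc, "unsupported_variant")) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(id = v$id, transcript = tx$id, reason = cc$reason)
        next
      }
      if (cc$variant_class == "synonymous") {
        skipped[[length(skipped) + 1L]] <-
          data.frame(id = v$id, transcript = tx$id, reason = "synonymous")
        next
      }
      rp <- rule_score(cc, lambda)
      cons <- if (!is.null(tracks)) conservation_features(v, tracks)
              else list(scores = c(gerp = NA, phylop = NA, siphy = NA),
                        missing = TRUE)
      if (is.null(rp)) {
        fv <- encode_variant(cc, tracks, scales, lambda, w)
        rp <- predict(model, fv)
      }
      ext <- .lookup_external(external, v, tx$id)
      res <- vote_ensemble(rp,
                           standardize_external(ext[["pp2"]], "polyphen2"),
                           standardize_external(ext[["sift"]], "sift"))
      out[[length(out) + 1L]] <- data.frame(
        variant = v$id, transcript = tx$id, gene = tx$gene,
        variant_class = cc$variant_class,
        final_class = res$class, final_score = res$score,
        rf_score = res$rf_score, pp2_std = res$pp2_std,
        sift_std = res$sift_std, decided_by = res$decided_by,
        cons_gerp = unname(cons$scores[1]),
        cons_phylop = unname(cons$scores[2]),
        cons_siphy = unname(cons$scores[3]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variant = character(), transcript = character())
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  res
}
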