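# Amphiphilic pseudo amino acid composition (PseAAC) encoding of peptide
# snippets around a coding change.

#' The 20 standard amino acids, alphabetical one-letter order
#'
#' This order fixes the first 20 entries of every PseAAC vector.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Raw hydrophobicity (Tanford/Chou) and hydrophilicity (Hopp-Woods) scales.
.RAW_H1 <- c(A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
             G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
             M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
             S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)

.RAW_H2 <- c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
             G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
             M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
             S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

#' Normalize hydrophobicity/hydrophilicity scales
#'
#' Centers each scale to mean 0 and scales it to unit standard deviation
#' over the 20 standard amino acids (population convention, denominator 20,
#' as in the amphiphilic PseAAC literature).
#'
#' @param raw_h1 Named numeric vector of raw hydrophobicity values, one per
#'   standard amino acid (one-letter names).
#' @param raw_h2 Named numeric vector of raw hydrophilicity values.
#' @return An object of class \code{aa_scales}: a list with normalized
#'   numeric vectors \code{h1} and \code{h2} indexed by amino acid.
#' @examples
#' sc <- normalize_scales()
#' round(mean(sc$h1), 12)  # 0
#' @export
normalize_scales <- function(raw_h1 = .RAW_H1, raw_h2 = .RAW_H2) {
  norm1 <- function(raw, what) {
    missing <- setdiff(AA_ALPHABET20, names(raw))
    if (length(missing))
      stop("scale '", what, "' is missing amino acid(s): ",
           paste(missing, collapse = ", "))
    x <- raw[AA_ALPHABET20]
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop("scale '", what, "' has zero variance")
    (x - mean(x)) / s
  }
  structure(list(h1 = norm1(raw_h1, "h1"), h2 = norm1(raw_h2, "h2")),
            class = "aa_scales")
}

#' Read raw amphiphilic scales from a TSV file
#'
#' Expects columns \code{aa}, \code{h1_raw}, \code{h2_raw}.
#' @param path TSV file path.
#' @return Normalized \code{aa_scales} (see \code{\link{normalize_scales}}).
#' @export
read_scales <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  normalize_scales(stats::setNames(tab$h1_raw, tab$aa),
                   stats::setNames(tab$h2_raw, tab$aa))
}

#' Extract wild and mutant peptide snippets around the first changed residue
#'
#' Takes up to 20 residues on either side of the first mutated amino acid in
#' each protein (a 41-residue window in the interior), truncating at the
#' protein termini; no padding is ever added.  The mutant window is anchored
#' at the first residue where the mutant differs from the wild protein
#' (clamped into the mutant sequence when the mutant is shorter, e.g. after
#' a premature stop).
#'
#' @param cc A \code{coding_change} (see \code{\link{apply_variant}}).
#' @param flank Number of residues taken on each side of the anchor.
#' @return List with elements \code{wild} and \code{mutant}, each a list of
#'   \code{sequence}, \code{anchor} (1-based index of the changed residue
#'   within the snippet) and \code{L}.
#' @export
extract_snippets <- function(cc, flank = 20L) {
  if (cc$variant_class == "synonymous")
    stop("synonymous change has no snippet to extract")
  window <- function(protein, anchor) {
    n <- nchar(protein)
    if (n == 0L)
      return(list(sequence = "", anchor = 0L, L = 0L))
    anchor <- min(max(anchor, 1L), n)
    from <- max(1L, anchor - flank)
    to <- min(n, anchor + flank)
    list(sequence = substr(protein, from, to),
         anchor = anchor - from + 1L, L = to - from + 1L)
  }
  list(wild   = window(cc$wild_protein,   cc$first_changed_aa),
       mutant = window(cc$mutant_protein, cc$first_changed_aa))
}

#' Tiered hydrophobicity/hydrophilicity correlation factors
#'
#' For tier k = 1..lambda, couples residues at separation k: the tier's
#' hydrophobicity factor is the mean over i of h1(A_i) * h1(A_{i+k}) and its
#' hydrophilicity factor the analogous h2 product mean.  Averaging by the
#' number of coupled pairs (L - k) keeps factors comparable across snippet
#' lengths; set \code{tau_average = FALSE} for the raw-sum variant.
#'
#' @param sequence Amino-acid string of length L.
#' @param scales Normalized \code{aa_scales}.
#' @param lambda Number of tiers; requires L >= lambda + 1.
#' @param tau_average Average each tier by (L - k) (default) or keep the sum.
#' @return Numeric vector of length 2*lambda, interleaved
#'   (h1 tier 1, h2 tier 1, h1 tier 2, ...).
#' @export
correlation_tiers <- function(sequence, scales, lambda,
                              tau_average = TRUE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), AA_ALPHABET20)
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  L <- length(aa)
  if (lambda == 0L) return(numeric(0))
  if (L < lambda + 1L)
    stop("sequence of length ", L, " too short for lambda = ", lambda,
         " (needs length >= lambda + 1)", call. = FALSE)
  v1 <- unname(scales$h1[aa])
  v2 <- unname(scales$h2[aa])
  tau <- numeric(2L * lambda)
  for (k in seq_len(lambda)) {
    i <- seq_len(L - k)
    s1 <- sum(v1[i] * v1[i + k])
    s2 <- sum(v2[i] * v2[i + k])
    if (tau_average) {
      s1 <- s1 / (L - k)
      s2 <- s2 / (L - k)
    }
    tau[2L * k - 1L] <- s1
    tau[2L * k] <- s2
  }
  tau
}

#' Amphiphilic PseAAC vector of a peptide snippet
#'
#' Builds the 20 + 2*lambda representation: the first 20 entries are the
#' amino-acid frequencies f_u and the tail holds the weighted tier
#' correlation factors, all divided by the common denominator
#' sum(f) + w * sum(tau) so the full vector sums to 1.
#'
#' @param sequence Amino-acid string (length >= lambda + 1).
#' @param scales Normalized \code{aa_scales}.
#' @param lambda Tier count; the vector has 20 + 2*lambda entries.
#' @param w Weight of the correlation block (> 0).
#' @param tau_average See \code{\link{correlation_tiers}}.
#' @return Object of class \code{pseaac}: numeric vector of length
#'   20 + 2*lambda with attributes \code{lambda} and \code{w}.
#' @examples
#' sc <- normalize_scales()
#' p <- pseaac_vector(strrep("ACDEFGHIKLMNP", 3), sc, lambda = 12, w = 0.1)
#' length(p); sum(p)
#' @export
pseaac_vector <- function(sequence, scales, lambda = 12L, w = 0.1,
                          tau_average = TRUE) {
  stopifnot(w > 0)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(aa), AA_ALPHABET20)
  if (length(bad))
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  f <- as.vector(table(factor(aa, levels = AA_ALPHABET20))) / length(aa)
  tau <- correlation_tiers(sequence, scales, lambda, tau_average)
  D <- sum(f) + w * sum(tau)
  if (D == 0) stop("degenerate PseAAC denominator (sum f + w sum tau = 0)")
  structure(c(f / D, w * tau / D), lambda = as.integer(lambda), w = w,
            class = "pseaac")
}

#' Element-wise wild-minus-mutant PseAAC difference
#'
#' The difference of the two snippet encodings is the variant's sequence
#' feature block; identical snippets give the zero vector.
#'
#' @param wild,mutant \code{pseaac} vectors built with the same lambda and w.
#' @return Plain numeric vector of length 20 + 2*lambda.
#' @export
pseaac_diff <- function(wild, mutant) {
  if (length(wild) != length(mutant) ||
      !identical(attr(wild, "lambda"), attr(mutant, "lambda")))
    stop("PseAAC vectors differ in lambda/length; re-encode both sides")
  if (!isTRUE(all.equal(attr(wild, "w"), attr(mutant, "w"))))
    stop("PseAAC vectors built with different weights w")
  as.numeric(wild) - as.numeric(mutant)
}

#' @export
print.pseaac <- function(x, ...) {
  cat("Amphiphilic PseAAC vector: lambda =", attr(x, "lambda"),
      ", w =", attr(x, "w"), ", length", length(x), "\n")
  print(round(as.numeric(x), 4))
  invisible(x)
}
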