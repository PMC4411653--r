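# Reference, gene-model and variant I/O, and projection of a genomic
# variant onto a transcript's protein.
#
# Coordinates are 0-based half-open internally; VCF positions (1-based)
# are converted at the boundary.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector, one uppercase sequence per chromosome
#'   (names truncated at the first whitespace).
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Construct a transcript model
#'
#' @param id Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exon_starts,exon_ends Integer vectors, 0-based half-open, sorted.
#' @param cds_start,cds_end CDS span (0-based half-open), inclusive of the
#'   stop codon, falling within the exon union.
#' @param gene Gene symbol.
#' @return Object of class \code{transcript}.
#' @export
transcript <- function(id, chrom, strand, exon_starts, exon_ends,
                       cds_start, cds_end, gene = id) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends))
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (is.unsorted(exon_starts, strictly = TRUE) ||
      any(exon_ends <= exon_starts) ||
      any(utils::head(exon_ends, -1) > utils::tail(exon_starts, -1)))
    stop("transcript ", id, ": exons must be sorted and non-overlapping")
  tx <- structure(list(id = id, chrom = chrom, strand = strand,
                       exon_starts = exon_starts, exon_ends = exon_ends,
                       cds_start = as.integer(cds_start),
                       cds_end = as.integer(cds_end), gene = gene),
                  class = "transcript")
  cds <- .cds_intervals(tx)
  if (nrow(cds) == 0L || sum(cds[, 2] - cds[, 1]) == 0L)
    stop("transcript ", id, ": empty CDS")
  if (cds_start < exon_starts[1] || cds_end > exon_ends[length(exon_ends)])
    stop("transcript ", id, ": CDS outside exons")
  tx
}

#' @export
print.transcript <- function(x, ...) {
  cat("Transcript", x$id, sprintf("(%s)", x$gene), "on", x$chrom, x$strand,
      "\n  exons:", length(x$exon_starts),
      " CDS:", x$cds_start, "-", x$cds_end, "\n")
  invisible(x)
}

# Exon intervals intersected with the CDS span; matrix of 0-based
# half-open rows in genomic order.
.cds_intervals <- function(tx) {
  s <- pmax(tx$exon_starts, tx$cds_start)
  e <- pmin(tx$exon_ends, tx$cds_end)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

.revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a nucleotide string from its first base, stopping at the first
# stop codon (which is not included).  Trailing partial codons are dropped;
# codons with ambiguous bases translate to "X".
.translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  pos <- 3L * seq_len(n) - 2L
  codons <- substring(nt, pos, pos + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
  paste(aa, collapse = "")
}

# Spliced sequence of 0-based half-open intervals on the + strand.
.spliced <- function(chrom_seq, intervals) {
  if (nrow(intervals) == 0L) return("")
  paste(substring(chrom_seq, intervals[, 1] + 1L, intervals[, 2]),
        collapse = "")
}

#' Spliced coding sequence and protein of a transcript
#'
#' @param tx A \code{transcript}.
#' @param genome Named character vector from \code{\link{read_reference}}.
#' @return List with \code{cds} (strand-oriented nucleotide string) and
#'   \code{protein} (translation truncated at the first stop).
#' @export
transcript_protein <- function(tx, genome) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq)) stop("chromosome ", tx$chrom, " not in reference")
  cds <- .spliced(chrom_seq, .cds_intervals(tx))
  if (tx$strand == "-") cds <- .revcomp(cds)
  list(cds = cds, protein = .translate_nt(cds))
}

#' Read gene models (genePred/refFlat tab text or a minimal GTF subset)
#'
#' genePred columns: name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds (0-based half-open, comma-separated
#' lists); an optional 12th column is taken as the gene symbol.  For GTF,
#' \code{exon} and \code{CDS} features are grouped by \code{transcript_id}.
#'
#' @param path File path.
#' @param dialect \code{"genePred"} or \code{"gtf"}.
#' @return List of \code{\link{transcript}} objects.
#' @export
read_gene_model <- function(path, dialect = c("genePred", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "gtf") return(.read_gtf(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("genePred parse error at line ", i, ": expected >= 10 columns, got ",
           length(f))
    starts <- suppressWarnings(as.integer(strsplit(f[9], ",")[[1]]))
    ends <- suppressWarnings(as.integer(strsplit(f[10], ",")[[1]]))
    if (anyNA(starts) || anyNA(ends) || length(starts) != as.integer(f[8]))
      stop("genePred parse error at line ", i, ": bad exon lists")
    out[[i]] <- transcript(id = f[1], chrom = f[2], strand = f[3],
                           exon_starts = starts, exon_ends = ends,
                           cds_start = as.integer(f[6]),
                           cds_end = as.integer(f[7]),
                           gene = if (length(f) >= 12L) f[12] else f[1])
  }
  out
}

.read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("exon", "CDS"), ]
  if (!nrow(df)) return(list())
  out <- list()
  for (txid in unique(df$transcript_id)) {
    d <- df[df$transcript_id == txid, ]
    ex <- d[d$type == "exon", ]
    cd <- d[d$type == "CDS", ]
    if (!nrow(ex)) ex <- cd
    if (!nrow(cd)) stop("transcript ", txid, " has no CDS features")
    ord <- order(ex$start)
    gene <- if ("gene_id" %in% names(d) && !is.na(d$gene_id[1]))
      d$gene_id[1] else txid
    out[[length(out) + 1L]] <- transcript(
      id = txid, chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      exon_starts = ex$start[ord] - 1L, exon_ends = ex$end[ord],
      cds_start = min(cd$start) - 1L, cds_end = max(cd$end), gene = gene)
  }
  out
}

#' Read variants from a VCF file
#'
#' Multi-allelic records are decomposed into one variant per ALT allele.
#'
#' @param path VCF file.
#' @param genome Optional reference from \code{\link{read_reference}}; when
#'   supplied, each REF allele is checked against it.
#' @return data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{id}, in file order.
#' @export
read_variants <- function(path, genome = NULL) {
  fix <- vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE))
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (alt in alts)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = toupper(fix[i, "REF"]), alt = toupper(alt),
        id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".")
          sprintf("%s:%s:%s>%s", fix[i, "CHROM"], fix[i, "POS"],
                  fix[i, "REF"], alt) else fix[i, "ID"],
        stringsAsFactors = FALSE)
  }
  v <- do.call(rbind, rows)
  if (is.null(v))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      id = character(), stringsAsFactors = FALSE))
  if (!is.null(genome)) {
    for (i in seq_len(nrow(v))) {
      have <- substring(genome[[v$chrom[i]]], v$pos[i],
                        v$pos[i] + nchar(v$ref[i]) - 1L)
      if (!identical(have, v$ref[i]))
        stop("REF mismatch for record ", v$id[i], ": VCF says ", v$ref[i],
             ", reference has ", have)
    }
  }
  v
}

# Trim the shared prefix then shared suffix of ref/alt; returns the minimal
# representation and the 1-based position of its first base.
.trim_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L); alt <- substring(alt, 2L); pos <- pos + 1L
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  list(pos = pos, ref = ref, alt = alt)
}

.not_coding <- function(reason)
  structure(list(reason = reason), class = "not_coding")

.unsupported <- function(reason)
  structure(list(reason = reason), class = "unsupported_variant")

#' Apply a genomic variant to a transcript
#'
#' Edits the chromosome sequence, rebuilds the (coordinate-shifted) spliced
#' CDS and translates wild and mutant proteins.  The mutant translation may
#' run past the annotated stop (frameshift, stop-loss): downstream exonic
#' and then genomic sequence is appended until the first in-frame stop, so
#' the mutant protein is always stop-free and truncated at its first stop.
#'
#' @param tx A \code{\link{transcript}}.
#' @param genome Named character vector of chromosome sequences.
#' @param v One variant: list or one-row data.frame with \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}, optional \code{id}.
#' @param max_extension Cap (nt) on downstream sequence scanned for a new
#'   stop codon after frameshift/stop-loss.
#' @return A \code{coding_change} (transcript_id, wild/mutant proteins,
#'   variant_class, first_changed_aa, lengths), or a \code{not_coding} /
#'   \code{unsupported_variant} signal object for variants the scorer
#'   skips (outside the CDS, >60 nt, splice/start-codon-spanning indels,
#'   off-chromosome, REF mismatch raises an error).
#' @export
apply_variant <- function(tx, genome, v, max_extension = 9000L) {
  chrom_seq <- genome[[tx$chrom]]
  if (is.null(chrom_seq) || !identical(as.character(v$chrom), tx$chrom))
    return(.not_coding("different chromosome"))
  pos <- as.integer(v$pos)
  ref <- toupper(as.character(v$ref)); alt <- toupper(as.character(v$alt))
  if (max(nchar(ref), nchar(alt)) - 1L > 60L)
    return(.unsupported("indel longer than 60 nt"))
  have <- substring(chrom_seq, pos, pos + nchar(ref) - 1L)
  if (!identical(have, ref))
    stop("REF mismatch at ", tx$chrom, ":", pos, " (VCF ", ref,
         ", reference ", have, ")")

  trimmed <- .trim_alleles(pos, ref, alt)
  cds <- .cds_intervals(tx)
  # 0-based span of reference bases actually affected
  t0 <- trimmed$pos - 1L
  span_len <- nchar(trimmed$ref)
  affected <- if (span_len > 0L) c(t0, t0 + span_len)
              else c(t0 - 1L, t0 + 1L)  # insertion: between flanking bases
  in_cds <- any(affected[2] > cds[, 1] & affected[1] < cds[, 2])
  if (!in_cds) return(.not_coding("variant outside CDS"))

  is_indel <- nchar(trimmed$ref) != nchar(trimmed$alt)
  if (is_indel) {
    # reject indels not contained in a single exon (splice-spanning)
    within_one <- any(t0 >= cds[, 1] & (t0 + max(span_len, 1L)) <= cds[, 2])
    if (!within_one)
      return(.unsupported("indel spans a splice junction or CDS boundary"))
    # reject indels touching the start codon
    start_codon <- if (tx$strand == "+") c(tx$cds_start, tx$cds_start + 3L)
                   else c(tx$cds_end - 3L, tx$cds_end)
    if (affected[2] > start_codon[1] && affected[1] < start_codon[2])
      return(.unsupported("indel disrupts the start codon"))
  }

  wild_cds <- .spliced(chrom_seq, cds)
  if (tx$strand == "-") wild_cds <- .revcomp(wild_cds)
  wild_protein <- .translate_nt(wild_cds)

  # apply the (untrimmed) edit to the chromosome and shift coordinates
  e0 <- pos - 1L
  elen <- nchar(ref)
  delta <- nchar(alt) - elen
  mut_seq <- paste0(substr(chrom_seq, 1L, e0), alt,
                    substring(chrom_seq, e0 + elen + 1L))
  shift <- function(x) ifelse(x >= e0 + elen, x + delta,
                              ifelse(x > e0, pmin(x, e0 + elen + delta), x))
  m_ex_s <- shift(tx$exon_starts); m_ex_e <- shift(tx$exon_ends)
  m_cds_s <- shift(tx$cds_start); m_cds_e <- shift(tx$cds_end)
  s <- pmax(m_ex_s, m_cds_s); e <- pmin(m_ex_e, m_cds_e)
  mut_cds_iv <- cbind(s[e > s], e[e > s])
  mut_cds <- .spliced(mut_seq, mut_cds_iv)

  # downstream extension in transcript orientation, for lost stops
  if (tx$strand == "+") {
    tail3 <- .spliced(mut_seq, {
      s2 <- pmax(m_ex_s, m_cds_e); e2 <- m_ex_e
      cbind(s2[e2 > s2], e2[e2 > s2])
    })
    gend <- m_ex_e[length(m_ex_e)]
    ext <- substring(mut_seq, gend + 1L,
                     min(nchar(mut_seq), gend + max_extension))
    mut_full <- paste0(mut_cds, tail3, ext)
  } else {
    tail3 <- .spliced(mut_seq, {
      s2 <- m_ex_s; e2 <- pmin(m_ex_e, m_cds_s)
      cbind(s2[e2 > s2], e2[e2 > s2])
    })
    gstart <- m_ex_s[1]
    ext <- substring(mut_seq, max(1L, gstart - max_extension + 1L), gstart)
    mut_full <- paste0(.revcomp(mut_cds), .revcomp(tail3), .revcomp(ext))
  }
  mut_protein <- .translate_nt(mut_full)
  # a stop-free runaway frame is truncated to something sane
  if (nchar(mut_protein) > nchar(wild_protein) + max_extension %/% 3L)
    mut_protein <- substr(mut_protein, 1L,
                          nchar(wild_protein) + max_extension %/% 3L)

  .coding_change(tx, v, wild_protein, mut_protein, delta)
}

.coding_change <- function(tx, v, wild, mut, delta_nt) {
  lw <- nchar(wild); lm <- nchar(mut)
  n <- min(lw, lm)
  first <- NA_integer_
  if (n > 0L) {
    wa <- utf8ToInt(substr(wild, 1L, n)); ma <- utf8ToInt(substr(mut, 1L, n))
    d <- which(wa != ma)
    if (length(d)) first <- d[1]
  }
  if (is.na(first)) {
    if (lw == lm) {
      cls <- "synonymous"; first <- 0L
    } else first <- n + 1L  # pure extension or truncation
  }
  if (!exists("cls", inherits = FALSE)) {
    if (delta_nt %% 3L != 0L) {
      cls <- "frameshift"
    } else {
      expected <- lw + delta_nt %/% 3L
      if (lm < expected && lm < lw) cls <- "stop_gain"
      else if (lm > expected || (delta_nt == 0L && lm > lw)) cls <- "stop_loss"
      else if (delta_nt == 0L) cls <- "missense"
      else if (delta_nt > 0L) cls <- "inframe_insertion"
      else {
        tr <- .trim_alleles(1L, v$ref, v$alt)
        cls <- if (nchar(tr$alt) == 0L) "inframe_deletion" else "inframe_indel"
      }
    }
  }
  structure(list(
    transcript_id = tx$id, gene = tx$gene,
    chrom = as.character(v$chrom), pos = as.integer(v$pos),
    ref = as.character(v$ref), alt = as.character(v$alt),
    wild_protein = wild, mutant_protein = mut,
    variant_class = cls, first_changed_aa = as.integer(first),
    protein_len_wild = lw, protein_len_mut = lm), class = "coding_change")
}

#' @export
print.coding_change <- function(x, ...) {
  cat("Coding change on", x$transcript_id, paste0("(", x$gene, "):"),
      x$variant_class, "\n  ", x$chrom, ":", x$pos, " ", x$ref, ">", x$alt,
      "\n  protein ", x$protein_len_wild, " -> ", x$protein_len_mut,
      " aa; first changed residue ", x$first_changed_aa, "\n", sep = "")
  invisible(x)
}

#' Training-set stratum of a coding change
#'
#' Synonymous changes and frameshift/stop-causing/stop-disrupting variants
#' are held out of the balanced training/evaluation core.
#'
#' @param cc A \code{coding_change}.
#' @return \code{"core"}, \code{"excluded_syn"} or \code{"excluded_fr_sc_sd"}.
#' @export
classify_for_training <- function(cc) {
  switch(cc$variant_class,
         synonymous = "excluded_syn",
         frameshift = ,
         stop_gain = ,
         stop_loss = "excluded_fr_sc_sd",
         "core")
}
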