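# Synthetic study generator: toy genome and gene models, labeled variants
# with a plantable hydropathy-shift signal, smooth conservation tracks and
# mock external predictor scores.  Everything the pipeline consumes can be
# produced offline and deterministically from one seed.

#' Simulation configuration
#'
#' @param n_genes Number of transcripts in the toy genome.
#' @param mean_cds_codons Mean CDS length in codons.
#' @param n_variants Number of labeled variants to draw.
#' @param damaging_fraction Fraction of variants labeled damaging.
#' @param signal_strength In [0, 1]: 0 makes damaging and tolerated
#'   substitutions exchangeable; 1 makes damaging variants strongly prefer
#'   substitutions across the hydropathy axis and high-conservation sites.
#' @param indel_fraction Fraction of variants that are indels (mixed
#'   in-frame and frameshift, <= 60 nt).
#' @param external_accuracy Probability a mock external tool calls the
#'   planted label correctly.
#' @param external_missing Length-2 numeric: per-tool missing rate
#'   (PolyPhen2, SIFT).
#' @param seed Master seed; fixes every downstream artifact.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 30L, mean_cds_codons = 250L,
                       n_variants = 2000L, damaging_fraction = 0.5,
                       signal_strength = 1, indel_fraction = 0.1,
                       external_accuracy = 0.9,
                       external_missing = c(pp2 = 0.1, sift = 0.1),
                       seed = 1L) {
  stopifnot(damaging_fraction >= 0, damaging_fraction <= 1,
            signal_strength >= 0, signal_strength <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 mean_cds_codons = as.integer(mean_cds_codons),
                 n_variants = as.integer(n_variants),
                 damaging_fraction = damaging_fraction,
                 signal_strength = signal_strength,
                 indel_fraction = indel_fraction,
                 external_accuracy = external_accuracy,
                 external_missing = external_missing,
                 seed = as.integer(seed)), class = "sim_config")
}

.CODONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

.rand_coding_codons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  pool <- names(gc)[gc != "*" & gc != "M"]
  sample(pool, n, replace = TRUE)
}

#' Simulate a toy reference genome with gene models
#'
#' Builds \code{n_genes} protein-coding transcripts (valid start/stop, no
#' internal stop) on two chromosomes; about half are multi-exon and both
#' strands are represented.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return List with \code{genome} (named character vector) and
#'   \code{transcripts} (list of \code{\link{transcript}}).
#' @export
simulate_reference <- function(cfg) .with_seed(cfg$seed, {
  chrom_seqs <- list(chrS1 = character(), chrS2 = character())
  offsets <- c(chrS1 = 0L, chrS2 = 0L)
  txs <- list()
  for (g in seq_len(cfg$n_genes)) {
    chrom <- names(offsets)[(g %% 2L) + 1L]
    strand <- if (g %% 4L < 2L) "+" else "-"
    ncod <- max(60L, round(stats::rnorm(1, cfg$mean_cds_codons,
                                        cfg$mean_cds_codons / 5)))
    codons <- c("ATG", .rand_coding_codons(ncod - 2L),
                sample(c("TAA", "TAG", "TGA"), 1))
    cds <- paste(codons, collapse = "")
    if (strand == "-") cds <- .revcomp(cds)
    # split the genomic CDS into 1-3 exons with random introns
    n_exon <- sample(1:3, 1)
    cuts <- if (n_exon > 1L)
      sort(sample(seq(10L, nchar(cds) - 10L), n_exon - 1L)) else integer()
    pieces <- substring(cds, c(1L, cuts + 1L), c(cuts, nchar(cds)))
    introns <- replicate(max(0L, n_exon - 1L),
      paste(sample(c("A", "C", "G", "T"), sample(60:180, 1),
                   replace = TRUE), collapse = ""))
    lead <- paste(sample(c("A", "C", "G", "T"), sample(120:300, 1),
                         replace = TRUE), collapse = "")
    start0 <- offsets[[chrom]] + nchar(lead)
    block <- lead
    ex_s <- integer(); ex_e <- integer()
    at <- start0
    for (e in seq_len(n_exon)) {
      ex_s[e] <- at
      ex_e[e] <- at + nchar(pieces[e])
      block <- paste0(block, pieces[e])
      at <- ex_e[e]
      if (e < n_exon) {
        block <- paste0(block, introns[e])
        at <- at + nchar(introns[[e]])
      }
    }
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], block)
    offsets[[chrom]] <- at
    txs[[g]] <- transcript(id = sprintf("TX%03d", g), chrom = chrom,
                           strand = strand, exon_starts = ex_s,
                           exon_ends = ex_e, cds_start = ex_s[1],
                           cds_end = ex_e[n_exon],
                           gene = sprintf("GENE%03d", g))
  }
  tail_pad <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                    collapse = "")
  genome <- vapply(chrom_seqs, function(p) paste0(paste(p, collapse = ""),
                                                  tail_pad), "")
  list(genome = genome, transcripts = txs)
})

# 1-based genomic positions of CDS bases in translation order, plus the
# exon-interval index of each base.
.cds_base_map <- function(tx) {
  iv <- .cds_intervals(tx)
  pos <- unlist(lapply(seq_len(nrow(iv)),
                       function(i) seq(iv[i, 1] + 1L, iv[i, 2])))
  exon <- rep(seq_len(nrow(iv)), iv[, 2] - iv[, 1])
  if (tx$strand == "-") {
    pos <- rev(pos); exon <- rev(exon)
  }
  list(pos = pos, exon = exon)
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate labeled variants with a hydropathy-shift signal
#'
#' Damaging variants preferentially substitute residues across the
#' hydrophobicity/hydrophilicity axes (substitution choice weighted by
#' exp(2 * signal_strength * |dh1| + |dh2|)); tolerated variants prefer
#' conservative substitutions.  An \code{indel_fraction} of each class are
#' in-frame or frameshift indels confined to one exon.  Population
#' frequencies come from a two-component distribution so both the > 0.05
#' tolerated filter and the damaging frequency exclusion see work: 95\% of
#' damaging variants are rare (< 0.01) and 5\% common, 95\% of tolerated
#' candidates are common (> 0.05) and 5\% rare.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param ref Output of \code{\link{simulate_reference}}.
#' @return data.frame: chrom, pos, ref, alt, id, transcript, label,
#'   frequency, is_indel.
#' @export
simulate_variants <- function(cfg, ref) .with_seed(cfg$seed + 1L, {
  stopifnot(length(ref$transcripts) > 0)
  scales <- normalize_scales()
  gc <- Biostrings::GENETIC_CODE
  genome <- ref$genome
  seen <- new.env(hash = TRUE)
  rows <- vector("list", cfg$n_variants)
  n_done <- 0L
  tries <- 0L
  while (n_done < cfg$n_variants && tries < cfg$n_variants * 50L) {
    tries <- tries + 1L
    tx <- ref$transcripts[[sample.int(length(ref$transcripts), 1)]]
    damaging <- stats::runif(1) < cfg$damaging_fraction
    map <- .cds_base_map(tx)
    ncod <- length(map$pos) %/% 3L
    make_indel <- stats::runif(1) < cfg$indel_fraction

    if (!make_indel) {
      j <- sample(3:(ncod - 2L), 1)
      idx <- 3L * (j - 1L) + 1:3
      codon_pos <- map$pos[idx]
      coding_bases <- substring(genome[[tx$chrom]], codon_pos, codon_pos)
      if (tx$strand == "-") coding_bases <- .COMP[coding_bases]
      codon <- paste(coding_bases, collapse = "")
      aa0 <- gc[[codon]]
      cand <- list()
      for (k in 1:3) for (b in c("A", "C", "G", "T")) {
        if (b == coding_bases[k]) next
        nc <- coding_bases; nc[k] <- b
        aa1 <- gc[[paste(nc, collapse = "")]]
        if (aa1 == "*" || aa1 == aa0) next
        cand[[length(cand) + 1L]] <- list(k = k, b = b, aa1 = aa1)
      }
      if (!length(cand)) next
      d <- vapply(cand, function(cn)
        abs(scales$h1[[aa0]] - scales$h1[[cn$aa1]]) +
          abs(scales$h2[[aa0]] - scales$h2[[cn$aa1]]), 0)
      wgt <- exp((if (damaging) 2 else -2) * cfg$signal_strength * d)
      pick <- cand[[sample.int(length(cand), 1, prob = wgt)]]
      gpos <- codon_pos[pick$k]
      gref <- substring(genome[[tx$chrom]], gpos, gpos)
      galt <- if (tx$strand == "-") .COMP[[pick$b]] else pick$b
      vref <- gref; valt <- galt; vpos <- gpos
    } else {
      deletion <- stats::runif(1) < 0.5
      inframe <- stats::runif(1) < 0.6
      if (deletion) {
        k_nt <- if (inframe) 3L * sample(1:4, 1) else sample(1:2, 1)
        a <- 3L * (sample(3:(ncod - 6L), 1) - 1L) + 1L
        idx <- a:(a + k_nt - 1L)
        g <- map$pos[idx]
        if (max(g) - min(g) != k_nt - 1L ||
            length(unique(map$exon[idx])) != 1L) next
        anchor <- min(g) - 1L
        block <- substring(genome[[tx$chrom]], min(g), max(g))
        vpos <- anchor
        vref <- paste0(substring(genome[[tx$chrom]], anchor, anchor), block)
        valt <- substring(genome[[tx$chrom]], anchor, anchor)
      } else {
        k_nt <- if (inframe) 3L * sample(1:4, 1) else sample(1:2, 1)
        a <- 3L * (sample(3:(ncod - 6L), 1) - 1L) + 2L
        if (length(unique(map$exon[(a - 1L):(a + 1L)])) != 1L) next
        gpos <- map$pos[a]
        ins <- paste(sample(c("A", "C", "G", "T"), k_nt, replace = TRUE),
                     collapse = "")
        vpos <- gpos
        vref <- substring(genome[[tx$chrom]], gpos, gpos)
        valt <- paste0(vref, ins)
      }
    }
    key <- paste(tx$chrom, vpos, vref, valt, sep = ":")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    freq <- if (damaging) {
      if (stats::runif(1) < 0.05) stats::runif(1, 0.06, 0.2)
      else stats::runif(1, 0, 0.01)
    } else {
      if (stats::runif(1) < 0.05) stats::runif(1, 0, 0.049)
      else stats::runif(1, 0.051, 0.5)
    }
    n_done <- n_done + 1L
    rows[[n_done]] <- data.frame(
      chrom = tx$chrom, pos = vpos, ref = unname(vref), alt = unname(valt),
      id = sprintf("var%05d", n_done), transcript = tx$id,
      label = if (damaging) "damaging" else "tolerated",
      frequency = freq, is_indel = make_indel, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows[seq_len(n_done)])
})

#' Simulate three conservation tracks
#'
#' Smooth per-base background (moving-average of white noise) over every
#' CDS base, elevated at the planted damaging sites in proportion to
#' \code{signal_strength}; the three tracks use distinct scales, loosely
#' GERP-, phyloP- and SiPhy-like.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param ref Output of \code{\link{simulate_reference}}.
#' @param variants Output of \code{\link{simulate_variants}} (for the
#'   damaging site positions); may be \code{NULL}.
#' @return List of three \code{cons_track} objects (gerp, phylop, siphy).
#' @export
simulate_conservation <- function(cfg, ref, variants = NULL)
  .with_seed(cfg$seed + 2L, {
  specs <- list(gerp = list(sd = 1.5, mult = 1.5, off = 0),
                phylop = list(sd = 1.0, mult = 1.0, off = 0),
                siphy = list(sd = 3.0, mult = 3.0, off = 8))
  dmg <- if (!is.null(variants))
    variants[variants$label == "damaging", ] else NULL
  tracks <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    grl <- list()
    for (chrom in names(ref$genome)) {
      n <- nchar(ref$genome[[chrom]])
      noise <- stats::rnorm(n + 20L, 0, sp$sd)
      smooth <- as.numeric(stats::filter(noise, rep(1 / 21, 21),
                                         sides = 2))[11:(n + 10L)]
      score <- smooth * sqrt(21) + sp$off  # restore marginal sd
      if (!is.null(dmg)) {
        d <- dmg[dmg$chrom == chrom, ]
        if (nrow(d)) {
          at <- pmin(pmax(d$pos, 1L), n)
          for (p in at) {
            lo <- max(1L, p - 2L); hi <- min(n, p + 2L)
            score[lo:hi] <- score[lo:hi] +
              sp$mult * cfg$signal_strength +
              stats::rnorm(hi - lo + 1L, 0, sp$sd / 2)
          }
        }
      }
      grl[[chrom]] <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(seq_len(n), seq_len(n)),
        score = round(score, 3))
    }
    tracks[[nm]] <- new_cons_track(nm,
      suppressWarnings(do.call(c, unname(grl))))
  }
  tracks
})

#' Simulate mock external predictor scores
#'
#' Per variant and tool, the score is missing with the configured rate;
#' otherwise it lands on the side of the tool's threshold matching the
#' planted label with probability \code{external_accuracy}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param variants Output of \code{\link{simulate_variants}}.
#' @return data.frame: chrom, pos, ref, alt, pp2_score, sift_score (NA =
#'   no prediction).
#' @export
simulate_external_scores <- function(cfg, variants)
  .with_seed(cfg$seed + 3L, {
  n <- nrow(variants)
  dmg <- variants$label == "damaging"
  draw <- function(tool, missing_rate) {
    correct <- stats::runif(n) < cfg$external_accuracy
    say_damaging <- ifelse(correct, dmg, !dmg)
    raw <- if (tool == "pp2")
      ifelse(say_damaging, stats::runif(n, 0.447, 1),
             stats::runif(n, 0, 0.44))
    else
      ifelse(say_damaging, stats::runif(n, 0, 0.049),
             stats::runif(n, 0.051, 1))
    raw[stats::runif(n) < missing_rate] <- NA_real_
    round(raw, 3)
  }
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             pp2_score = draw("pp2", cfg$external_missing[[1]]),
             sift_score = draw("sift", cfg$external_missing[[2]]),
             stringsAsFactors = FALSE)
})

#' Run the whole generator and encode the labeled feature matrix
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param encode Also project and encode every variant (features element).
#' @param lambda,w PseAAC parameters for the encoding.
#' @return List: genome, transcripts, variants, tracks, external and (when
#'   \code{encode}) \code{features}, a labeled feature data.frame carrying
#'   \code{variant_class} and \code{frequency} for the dataset filters.
#' @export
simulate_study <- function(cfg, encode = TRUE, lambda = 12L, w = 0.1) {
  ref <- simulate_reference(cfg)
  variants <- simulate_variants(cfg, ref)
  tracks <- simulate_conservation(cfg, ref, variants)
  external <- simulate_external_scores(cfg, variants)
  out <- list(genome = ref$genome, transcripts = ref$transcripts,
              variants = variants, tracks = tracks, external = external,
              config = cfg)
  if (encode) {
    scales <- normalize_scales()
    tx_by_id <- stats::setNames(ref$transcripts,
                                vapply(ref$transcripts, `[[`, "", "id"))
    feats <- vector("list", nrow(variants))
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      cc <- apply_variant(tx_by_id[[v$transcript]], ref$genome, v)
      if (!inherits(cc, "coding_change")) next
      if (cc$variant_class == "synonymous") next
      row <- tryCatch(encode_variant(cc, tracks, scales, lambda, w,
                                     label = v$label),
                      short_sequence = function(e) NULL)
      if (is.null(row)) next
      row$variant_class <- cc$variant_class
      row$frequency <- v$frequency
      row$id <- v$id
      feats[[i]] <- row
    }
    out$features <- do.call(rbind, feats[!vapply(feats, is.null, TRUE)])
  }
  out
}

#' Write all simulated inputs to disk in their standard formats
#'
#' FASTA reference, genePred gene model, VCF variants, a label/frequency
#' TSV, three bedGraph conservation tracks and the external-score TSV.
#'
#' @param sim Output of \code{\link{simulate_study}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(ref = file.path(dir, "ref.fa"),
             genes = file.path(dir, "genes.genepred"),
             vcf = file.path(dir, "variants.vcf"),
             labels = file.path(dir, "labels.tsv"),
             gerp = file.path(dir, "gerp.bedGraph"),
             phylop = file.path(dir, "phylop.bedGraph"),
             siphy = file.path(dir, "siphy.bedGraph"),
             external = file.path(dir, "external.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              paths[["ref"]])
  gp <- vapply(sim$transcripts, function(tx) paste(
    tx$id, tx$chrom, tx$strand, tx$exon_starts[1],
    tx$exon_ends[length(tx$exon_ends)], tx$cds_start, tx$cds_end,
    length(tx$exon_starts),
    paste0(paste(tx$exon_starts, collapse = ","), ","),
    paste0(paste(tx$exon_ends, collapse = ","), ","),
    0L, tx$gene, sep = "\t"), "")
  writeLines(gp, paths[["genes"]])
  v <- sim$variants
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       v$chrom, v$pos, v$id, v$ref, v$alt)),
             paths[["vcf"]])
  utils::write.table(v[c("id", "chrom", "pos", "ref", "alt", "transcript",
                         "label", "frequency")],
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in c("gerp", "phylop", "siphy"))
    rtracklayer::export(sim$tracks[[nm]]$gr, paths[[nm]],
                        format = "bedGraph")
  utils::write.table(sim$external, paths[["external"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
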