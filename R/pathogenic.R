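## Sensitivity of callsets to known pathogenic / premutation TR expansions.
## Disease loci carry bp thresholds (motif-count thresholds are converted at
## load time, since public tables mix the two conventions) and an
## inheritance mode that sets the detection rule.

#' Read a disease-locus threshold table
#'
#' BED-style, tab-separated, no header, columns: chrom, start, end, gene,
#' motif, pathogenic_min, intermediate_min (`.` if absent), inheritance
#' (dominant / recessive / x_linked). Thresholds may be given in motif
#' counts by setting `unit = "motifs"`, in which case they are converted to
#' bp as count x motif length.
#'
#' @param path File path.
#' @param unit `"bp"` or `"motifs"`.
#' @return data.frame of disease loci with bp thresholds, 0-based half-open
#'   coordinates.
#' @export
read_disease_table <- function(path, unit = c("bp", "motifs")) {
  unit <- match.arg(unit)
  df <- utils::read.table(path, sep = "\t", header = FALSE, na.strings = ".",
                          col.names = c("chrom", "start", "end", "gene",
                                        "motif", "pathogenic_min",
                                        "intermediate_min", "inheritance"),
                          stringsAsFactors = FALSE)
  df$motif <- toupper(df$motif)
  if (unit == "motifs") {
    ml <- nchar(df$motif)
    df$pathogenic_min <- df$pathogenic_min * ml
    df$intermediate_min <- df$intermediate_min * ml
  }
  bad <- which(!is.na(df$intermediate_min) &
                 df$intermediate_min > df$pathogenic_min)
  if (length(bad)) {
    stop("intermediate_min exceeds pathogenic_min for ", df$gene[bad[1]])
  }
  stopifnot(all(df$inheritance %in% c("dominant", "recessive", "x_linked")))
  df
}

#' Match a VCF record position to a disease locus
#'
#' A record belongs to a disease locus when its start lies within the
#' tolerance window of the disease locus start (default +/- 50 bp); with
#' several candidates the nearest start wins.
#'
#' @param chrom,start Record coordinates (0-based start).
#' @param diseases Disease table from [read_disease_table()].
#' @param tolerance Window half-width in bp.
#' @return Row index into `diseases`, or NA.
#' @export
match_disease_locus <- function(chrom, start, diseases, tolerance = 50L) {
  cand <- which(diseases$chrom == chrom &
                  abs(start - diseases$start) <= tolerance)
  if (!length(cand)) return(NA_integer_)
  cand[which.min(abs(start - diseases$start[cand]))]
}

#' Apply the inheritance-mode detection rule to one call
#'
#' An allele counts as expanded when its length is greater than or equal to
#' the threshold. Dominant diseases require one expanded allele; recessive
#' diseases two; X-linked loci in hemizygous males require at least one
#' expanded allele regardless of how many alleles the caller reported.
#' Carriers of recessive conditions and samples of unknown sex at X-linked
#' loci are evaluated with the one-allele rule.
#'
#' @param allele_lengths Numeric vector of called allele lengths (bp).
#' @param disease One row of a disease table.
#' @param threshold_kind `"pathogenic"` or `"intermediate"`.
#' @param sex `"male"`, `"female"` or NA (unknown).
#' @param carrier Evaluate with the carrier (one-allele) rule at a
#'   recessive locus.
#' @return TRUE if the call detects the expansion.
#' @export
detect_expansion <- function(allele_lengths, disease,
                             threshold_kind = c("pathogenic", "intermediate"),
                             sex = NA_character_, carrier = FALSE) {
  threshold_kind <- match.arg(threshold_kind)
  allele_lengths <- allele_lengths[!is.na(allele_lengths)]
  if (!length(allele_lengths)) return(FALSE)
  thr <- if (threshold_kind == "pathogenic") disease$pathogenic_min else {
    if (is.na(disease$intermediate_min)) {
      stop("no intermediate threshold for ", disease$gene)
    }
    disease$intermediate_min
  }
  n_expanded <- sum(allele_lengths >= thr)
  required <- switch(disease$inheritance,
                     dominant = 1L,
                     recessive = if (carrier) 1L else 2L,
                     x_linked = 1L)
  n_expanded >= required
}

#' Convert molecular sizes or thresholds by a motif-count offset
#'
#' Harmonizes values quoted under different locus definitions (e.g. adding
#' four motif units to sizes reported against a narrower repeat
#' definition).
#'
#' @param values Numeric bp values.
#' @param offset_motifs Signed motif-count offset.
#' @param motif_length Motif length in bp.
#' @return Adjusted bp values.
#' @export
adjust_threshold <- function(values, offset_motifs, motif_length) {
  stopifnot(motif_length >= 1)
  out <- values + offset_motifs * motif_length
  if (any(out < 0, na.rm = TRUE)) stop("adjusted value below zero")
  out
}

#' Sensitivity of callsets to planted or confirmed expansions
#'
#' For every expected expansion (truth rows with status pathogenic,
#' premutation or carrier; unaffected individuals are excluded), looks up
#' the sample's call at the disease locus, applies the inheritance-mode
#' rule at the status-appropriate threshold (intermediate for premutations,
#' pathogenic otherwise), and reports the detected fraction. Disease loci
#' with no call count as not detected.
#'
#' @param calls A [tr_calls()] table (one callset).
#' @param truths data.frame with columns `sample_id`, `gene`, `status`
#'   (pathogenic / premutation / carrier / unaffected), optional `sex`,
#'   optional `molecular_size`.
#' @param diseases Disease table from [read_disease_table()].
#' @param tolerance Positional window passed to [match_disease_locus()].
#' @param carrier_rule `"one_allele"` (default: a carrier of a recessive
#'   condition is detected when one allele is expanded) or `"two_allele"`
#'   (carriers are held to the full recessive rule and thus expected to be
#'   missed).
#' @return List with `sensitivity`, `n_expected`, `n_detected`, and
#'   `detections` (per-sample table with the called lengths alongside any
#'   molecular size estimate).
#' @export
sensitivity <- function(calls, truths, diseases, tolerance = 50L,
                        carrier_rule = c("one_allele", "two_allele")) {
  carrier_rule <- match.arg(carrier_rule)
  truths <- truths[truths$status != "unaffected", , drop = FALSE]
  if (!nrow(truths)) stop("sensitivity: empty truth set")
  rows <- vector("list", nrow(truths))
  for (i in seq_len(nrow(truths))) {
    gene_row <- match(truths$gene[i], diseases$gene)
    if (is.na(gene_row)) stop("unknown disease gene: ", truths$gene[i])
    dis <- diseases[gene_row, , drop = FALSE]
    cand <- calls[calls$sample_id == truths$sample_id[i] &
                    calls$chrom == dis$chrom &
                    !is.na(calls$reported_start) &
                    abs(calls$reported_start - dis$start) <= tolerance, ,
                  drop = FALSE]
    if (nrow(cand) > 1L) {
      cand <- cand[which.min(abs(cand$reported_start - dis$start)), ,
                   drop = FALSE]
    }
    lens <- if (nrow(cand)) c(cand$a1_len[1], cand$a2_len[1]) else numeric(0)
    kind <- if (truths$status[i] == "premutation") "intermediate" else
      "pathogenic"
    sex <- if ("sex" %in% names(truths)) truths$sex[i] else NA_character_
    det <- if (length(lens)) {
      detect_expansion(lens, dis, kind, sex = sex,
                       carrier = truths$status[i] == "carrier" &&
                         carrier_rule == "one_allele")
    } else FALSE
    rows[[i]] <- data.frame(
      sample_id = truths$sample_id[i], gene = truths$gene[i],
      status = truths$status[i],
      called = nrow(cand) > 0L,
      a1_len = if (length(lens)) lens[1] else NA_integer_,
      a2_len = if (length(lens)) lens[2] else NA_integer_,
      molecular_size = if ("molecular_size" %in% names(truths))
        truths$molecular_size[i] else NA_real_,
      detected = det, stringsAsFactors = FALSE)
  }
  detections <- do.call(rbind, rows)
  list(sensitivity = mean(detections$detected),
       n_expected = nrow(detections),
       n_detected = sum(detections$detected),
       detections = detections)
}
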