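#' The six canonical Gram-positive luxI/luxR cassettes
#'
#' Gene coordinates, strands and locus tags of the six canonical
#' luxI/luxR cassettes reported in Gram-positive bacteria
#' (*Asanoa ferruginea* NRRL B-16430, three copies; *Mumia flava* MUSC 201;
#' *Streptomyces purpurogeneiscleroticus* NRRL B-2952;
#' *Syntrophaceticus schinkii* Sp3), assembled from the published RefSeq
#' locus annotations. Strands follow the annotated transcription arrows.
#' When `with_intervening = TRUE`, synthetic filler genes of class `other`
#' are placed inside the annotated gaps to reproduce the reported
#' intervening-gene counts (2 for the *M. flava* pair, more than 7 for the
#' two widely spaced pairs); their coordinates are invented, as the
#' annotations report only the counts.
#'
#' @param with_intervening add synthetic intervening `other` genes
#'   (default `TRUE`).
#' @return a `gene_features` table.
#' @export
grampos_cassette_features <- function(with_intervening = TRUE) {
  f <- data.frame(
    replicon_id = c(rep("A_ferruginea_scf1", 2), rep("A_ferruginea_scf2", 2),
                    rep("A_ferruginea_scf3", 2), rep("M_flava_scf1", 2),
                    rep("S_purpurogeneiscleroticus_scf1", 2),
                    rep("S_schinkii_scf1", 2)),
    locus_tag = c("ADL14_22475", "ADL14_12710",
                  "ADL14_01860", "ADL14_01865",
                  "ADL14_09775", "ADL14_19790",
                  "LK11_10605", "LK11_10615",
                  "ADL19_05260", "ADL19_05265",
                  "SSCH_1100006", "SSCH_1110008"),
    start = c(117L, 3948L, 28172L, 29123L, 49208L, 49967L,
              94575L, 95914L, 37479L, 38419L, 3074L, 4194L),
    end = c(689L, 4550L, 28900L, 29698L, 49804L, 50611L,
            95183L, 96633L, 38207L, 38994L, 3310L, 4883L),
    strand = c("+", "-", "+", "+", "+", "-",
               "-", "+", "+", "+", "+", "-"),
    gene_class = c("luxR", "luxI", "luxR", "luxI", "luxR", "luxI",
                   "luxI", "luxR", "luxR", "luxI", "luxR", "luxI"),
    protein_id = c("A0A0M8ZBK1", "A0A0M8ZFU8", "A0A0N0U2C6", "A0A0N0BAZ2",
                   "A0A0M8ZHM1", "A0A0N0B7G7", "A0A0B2BR17", "A0A0B2BQK8",
                   "A0A0N0B8Y7", "A0A0N0B975", "A0A0B7MIQ5", "A0A0B7MAK3"),
    stringsAsFactors = FALSE)
  if (with_intervening) {
    filler <- function(replicon, prefix, starts, len)
      data.frame(replicon_id = replicon,
                 locus_tag = sprintf("%s_X%02d", prefix, seq_along(starts)),
                 start = as.integer(starts), end = as.integer(starts + len - 1),
                 strand = rep(c("+", "-"), length.out = length(starts)),
                 gene_class = "other", protein_id = NA_character_,
                 stringsAsFactors = FALSE)
    f <- rbind(
      f,
      # 8 genes between luxR 117..689 and luxI 3948..4550 (annotated X(>7))
      filler("A_ferruginea_scf1", "AFX1", 720 + (0:7) * 390, 300),
      # 2 genes between luxI 94575..95183 and luxR 95914..96633 (X(2))
      filler("M_flava_scf1", "MFX", c(95250, 95550), 240),
      # 8 genes between luxR 3074..3310 and luxI 4194..4883 (X(>7))
      filler("S_schinkii_scf1", "SSX", 3320 + (0:7) * 105, 90))
  }
  as_gene_features(f)
}

#' @rdname grampos_cassette_features
#' @return `grampos_cassette_patterns()`: data.frame pairing each cassette
#'   (`luxI_locus`, `luxR_locus`) with its annotated topology `pattern`.
#' @export
grampos_cassette_patterns <- function() {
  data.frame(
    luxI_locus = c("ADL14_12710", "ADL14_01865", "ADL14_19790",
                   "LK11_10605", "ADL19_05265", "SSCH_1110008"),
    luxR_locus = c("ADL14_22475", "ADL14_01860", "ADL14_09775",
                   "LK11_10615", "ADL19_05260", "SSCH_1100006"),
    pattern = c("R> X(>7) <I", "R>I>", "R><I",
                "<I X(2) R>", "R>I>", "R> X(>7) <I"),
    stringsAsFactors = FALSE)
}
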