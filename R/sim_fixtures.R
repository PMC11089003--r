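#' Generate a synthetic mouse-human ortholog table with a controlled
#' relation mix
#'
#' Emits (mouse_gene, human_gene) pairs realizing an exact mix of one-to-one,
#' one-to-many, many-to-one and unmapped relations. "Unmapped" mouse genes
#' are counted in `n_pairs` but produce no rows. One-to-many mouse genes map
#' to `fan_out` human genes each; many-to-one draws `fan_out` mouse genes
#' onto one shared human gene.
#'
#' @param n_pairs number of mouse-side relation slots to realize.
#' @param fractions named numeric: `one_to_one`, `one_to_many`, `many_to_one`,
#'   `unmapped`; must be non-negative and sum to 1. Class counts are
#'   `round(fractions * n_pairs)` with the remainder folded into one-to-one.
#' @param fan_out multiplicity used for the one-to-many / many-to-one classes.
#' @param seed integer seed.
#' @return tibble with columns `mouse_gene`, `human_gene`, `relation`.
#' @export
make_ortholog_table <- function(n_pairs,
                                fractions = c(one_to_one = 0.7,
                                              one_to_many = 0.1,
                                              many_to_one = 0.1,
                                              unmapped = 0.1),
                                fan_out = 2, seed = 1L) {
  need <- c("one_to_one", "one_to_many", "many_to_one", "unmapped")
  if (!all(need %in% names(fractions)))
    stop_bad_config("`fractions` must name one_to_one, one_to_many, many_to_one, unmapped")
  fractions <- fractions[need]
  if (any(fractions < 0)) stop_bad_config("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_bad_config("fractions must sum to 1")
  counts <- round(fractions * n_pairs)
  counts["one_to_one"] <- counts["one_to_one"] + (n_pairs - sum(counts))
  withr::with_seed(as.integer(seed), {
    mouse_pool <- sprintf("m_gene%05d", sample.int(99999, n_pairs * (1 + fan_out)))
    human_pool <- sprintf("h_GENE%05d", sample.int(99999, n_pairs * (1 + fan_out)))
    mi <- 0; hi <- 0
    take_m <- function(k) { v <- mouse_pool[mi + seq_len(k)]; mi <<- mi + k; v }
    take_h <- function(k) { v <- human_pool[hi + seq_len(k)]; hi <<- hi + k; v }
    rows <- list()
    if (counts["one_to_one"] > 0)
      rows$one_to_one <- tibble(mouse_gene = take_m(counts["one_to_one"]),
                                human_gene = take_h(counts["one_to_one"]),
                                relation = "one_to_one")
    if (counts["one_to_many"] > 0) {
      m <- take_m(counts["one_to_many"])
      rows$one_to_many <- tibble(
        mouse_gene = rep(m, each = fan_out),
        human_gene = take_h(counts["one_to_many"] * fan_out),
        relation = "one_to_many")
    }
    if (counts["many_to_one"] > 0) {
      h <- take_h(counts["many_to_one"])
      rows$many_to_one <- tibble(
        mouse_gene = take_m(counts["many_to_one"] * fan_out),
        human_gene = rep(h, each = fan_out),
        relation = "many_to_one")
    }
    out <- bind_rows(rows)
    if (nrow(out) == 0)
      out <- tibble(mouse_gene = character(), human_gene = character(),
                    relation = character())
    attr(out, "class_counts") <- counts
    out
  })
}

#' Predict PCR genotyping amplicon lengths for a deletion allele
#'
#' Given the wild-type amplicon length and the lengths of the deleted
#' segments (which must all lie between the primers), returns the wild-type
#' and mutant amplicon lengths. For the ApoE knockout allele used to genotype
#' xenograft host mice, a 755-bp wild-type amplicon with a 335-bp deletion
#' (148 bp of intron plus the first 187 bp of exon 4) yields a 420-bp mutant
#' amplicon.
#'
#' @param wt_amplicon_bp wild-type amplicon length in base pairs.
#' @param deletion_segments_bp numeric vector of deleted segment lengths
#'   (possibly empty).
#' @return tibble with `wt_amplicon_bp`, `deletion_bp`, `mutant_amplicon_bp`.
#' @export
predict_genotyping_amplicons <- function(wt_amplicon_bp,
                                         deletion_segments_bp = numeric()) {
  if (wt_amplicon_bp <= 0) abort("`wt_amplicon_bp` must be positive")
  if (any(deletion_segments_bp < 0)) abort("deletion segments must be >= 0")
  del <- sum(deletion_segments_bp)
  if (del >= wt_amplicon_bp)
    abort("total deletion meets or exceeds the amplicon; primers would be lost")
  tibble(wt_amplicon_bp = wt_amplicon_bp, deletion_bp = del,
         mutant_amplicon_bp = wt_amplicon_bp - del)
}
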