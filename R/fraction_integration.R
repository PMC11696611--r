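#' Regulation categories from three per-fraction DE calls
#'
#' Integrates the total-cytosolic, light-polysomal and heavy-polysomal
#' differential-abundance calls into regulation categories:
#' \itemize{
#'   \item \emph{post_transcriptional}: significant in the heavy and/or the
#'     light polysomal fraction but not in the total fraction;
#'   \item \emph{transcriptional}: significant in the total fraction but in
#'     neither polysomal fraction;
#'   \item \emph{mix}: significant in the total fraction and in the heavy
#'     and/or the light fraction;
#'   \item \emph{unchanged}: significant nowhere (explicit fourth category so
#'     the four classes partition every tested gene).
#' }
#' The gene universe is the union of the three tables; a gene missing from a
#' fraction (filtered out there) is treated as not significant in that
#' fraction and flagged through the `tested_*` columns. Direction consistency
#' across fractions is not required for a category; a `direction_consistent`
#' diagnostic (TRUE when all significant fractions share the fold-change
#' sign) is reported.
#'
#' @param de_total,de_light,de_heavy `de_result` data.frames from
#'   [de_test()] for the three fractions.
#' @return data.frame: gene_id, category (factor: post_transcriptional,
#'   transcriptional, mix, unchanged), sig_total/sig_light/sig_heavy,
#'   tested_total/tested_light/tested_heavy, direction_consistent.
#' @export
classify_regulation <- function(de_total, de_light, de_heavy) {
  tabs <- list(total = de_total, light = de_light, heavy = de_heavy)
  for (f in names(tabs)) {
    if (anyDuplicated(tabs[[f]]$gene_id)) {
      stop("duplicate gene id in ", f, " table: ",
           tabs[[f]]$gene_id[duplicated(tabs[[f]]$gene_id)][1L])
    }
  }
  genes <- Reduce(union, lapply(tabs, function(t) t$gene_id))
  sig <- lapply(tabs, function(t) {
    s <- unname(stats::setNames(t$significant, t$gene_id)[genes])
    ifelse(is.na(s), FALSE, s)
  })
  tested <- lapply(tabs, function(t) genes %in% t$gene_id)
  lfc <- lapply(tabs, function(t) {
    unname(stats::setNames(t$log2fc, t$gene_id)[genes])
  })

  poly <- sig$light | sig$heavy
  category <- ifelse(!sig$total & poly, "post_transcriptional",
              ifelse(sig$total & !poly, "transcriptional",
              ifelse(sig$total & poly, "mix", "unchanged")))

  signs <- matrix(unlist(Map(function(s, l) ifelse(s, sign(l), NA_real_),
                             sig, lfc)),
                  nrow = length(genes))
  direction_consistent <- apply(signs, 1L, function(r) {
    r <- r[!is.na(r)]
    length(r) <= 1L || all(r == r[1L])
  })

  data.frame(gene_id = genes,
             category = factor(category,
                               levels = c("post_transcriptional",
                                          "transcriptional", "mix",
                                          "unchanged")),
             sig_total = unname(sig$total),
             sig_light = unname(sig$light),
             sig_heavy = unname(sig$heavy),
             tested_total = tested$total,
             tested_light = tested$light,
             tested_heavy = tested$heavy,
             direction_consistent = direction_consistent,
             stringsAsFactors = FALSE)
}

#' Balanced accuracy of category recovery
#'
#' Mean per-class recall of predicted regulation categories against ground
#' truth, over the classes present in the truth.
#'
#' @param predicted Factor/character of predicted categories.
#' @param truth Factor/character of true categories (same length/order).
#' @return Single numeric in `[0, 1]`.
#' @export
balanced_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  classes <- unique(as.character(truth))
  mean(vapply(classes, function(cl) {
    mean(as.character(predicted)[truth == cl] == cl)
  }, numeric(1L)))
}
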