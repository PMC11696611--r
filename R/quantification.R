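#' Construct an LC-MS nucleoside measurement table
#'
#' Validates a peak-area table for nucleoside quantification: one row per
#' (sample, species, isotopologue) with a non-negative peak area.
#' Isotopologue 0 denotes the unlabeled species, 2 the 13C m+2 species.
#'
#' @param df data.frame with columns `sample_id`, `species`, `peak_area`,
#'   and optionally `isotopologue` (defaults to 0).
#' @return The validated data.frame.
#' @export
nucleoside_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("sample_id", "species", "peak_area") %in% names(df)))
  if (!("isotopologue" %in% names(df))) df$isotopologue <- 0L
  if (any(df$peak_area < 0)) stop("peak areas must be non-negative")
  if (any(df$isotopologue < 0 | df$isotopologue != floor(df$isotopologue))) {
    stop("isotopologue must be a non-negative integer")
  }
  key <- paste(df$sample_id, df$species, df$isotopologue)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, species, isotopologue): ", key[duplicated(key)][1L])
  }
  df
}

#' Ratio of modified to unmodified nucleoside peak areas
#'
#' The tRNA-modification level readout: modified area divided by the
#' corresponding unmodified nucleoside area (e.g. ncm5U/U, m3C/C, Gm/G)
#' within the same sample.
#'
#' @param modified,unmodified Numeric peak areas (vectors of equal length).
#' @return Numeric vector of ratios.
#' @export
mod_ratio <- function(modified, unmodified) {
  stopifnot(is.numeric(modified), is.numeric(unmodified),
            length(modified) == length(unmodified))
  if (any(modified < 0)) stop("modified peak areas must be non-negative")
  if (any(unmodified <= 0)) {
    stop("unmodified (denominator) peak areas must be positive")
  }
  modified / unmodified
}

#' Per-sample modification ratios from a measurement table
#'
#' @param tbl A [nucleoside_table()].
#' @param modified_species,unmodified_species Species labels (e.g.
#'   `"ncm5U34"` and `"U"`).
#' @return data.frame: sample_id, modified_species, unmodified_species,
#'   ratio.
#' @export
mod_ratio_table <- function(tbl, modified_species, unmodified_species) {
  tbl <- nucleoside_table(tbl)
  m <- tbl[tbl$species == modified_species & tbl$isotopologue == 0L, ]
  u <- tbl[tbl$species == unmodified_species & tbl$isotopologue == 0L, ]
  shared <- intersect(m$sample_id, u$sample_id)
  if (length(shared) == 0L) stop("no sample has both species")
  m <- m[match(shared, m$sample_id), ]
  u <- u[match(shared, u$sample_id), ]
  data.frame(sample_id = shared,
             modified_species = modified_species,
             unmodified_species = unmodified_species,
             ratio = mod_ratio(m$peak_area, u$peak_area),
             stringsAsFactors = FALSE)
}

#' m+2 isotopologue enrichment ratio
#'
#' The 13C-tracing readout: relative ratio between the 13C-labeled m+2
#' isotopologue and the corresponding unlabeled species, within the same
#' sample and species.
#'
#' @param tbl A [nucleoside_table()] containing isotopologue 0 and 2 rows.
#' @param species Species to quantify (e.g. `"ncm5U34"`, `"mcm5s2U34"`);
#'   default all species having both isotopologues.
#' @return data.frame: sample_id, species, ratio (m+2 area / m+0 area).
#' @export
isotopologue_ratio <- function(tbl, species = NULL) {
  tbl <- nucleoside_table(tbl)
  if (is.null(species)) species <- unique(tbl$species[tbl$isotopologue == 2L])
  out <- do.call(rbind, lapply(species, function(sp) {
    m2 <- tbl[tbl$species == sp & tbl$isotopologue == 2L, ]
    m0 <- tbl[tbl$species == sp & tbl$isotopologue == 0L, ]
    if (nrow(m2) == 0L || nrow(m0) == 0L) {
      stop("species '", sp, "' lacks m+2 and/or m+0 measurements")
    }
    shared <- intersect(m2$sample_id, m0$sample_id)
    if (length(shared) == 0L) {
      stop("no sample has both isotopologues of '", sp, "'")
    }
    m2 <- m2[match(shared, m2$sample_id), ]
    m0 <- m0[match(shared, m0$sample_id), ]
    if (any(m0$peak_area <= 0)) {
      stop("unlabeled (m+0) peak area must be positive for '", sp, "'")
    }
    data.frame(sample_id = shared, species = sp,
               ratio = m2$peak_area / m0$peak_area,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Expected natural-abundance m+2 fraction
#'
#' Binomial baseline for the m+2 isotopologue under natural 13C abundance:
#' choose(n, 2) p^2 (1-p)^(n-2) for a molecule with `n_carbons` carbons.
#' Provided as an optional diagnostic; reported tracing ratios are
#' uncorrected by default.
#'
#' @param n_carbons Number of carbon atoms (>= 2).
#' @param p13C Per-atom 13C probability (default natural abundance 0.0107).
#' @return Expected m+2 fraction.
#' @export
natural_abundance_m2 <- function(n_carbons, p13C = 0.0107) {
  stopifnot(n_carbons >= 2L, n_carbons == floor(n_carbons))
  if (p13C < 0 || p13C > 1) stop("p13C must lie in [0, 1]")
  stats::dbinom(2L, size = as.integer(n_carbons), prob = p13C)
}
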