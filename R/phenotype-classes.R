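# Agronomic trait classifications used to characterize the populations:
# maturity (days to flowering), grain shape (length/width ratio) and
# glutinous vs non-glutinous endosperm (iodine test), plus the
# population x trait cross-tabulations.

#' Maturity class from days to flowering
#'
#' Early (E <= 85 d), medium (85 < M <= 105 d), late (105 < L <= 135 d),
#' very late (VL > 135 d). Boundaries are inclusive exactly as stated, so 85
#' days is E and 105 days is M.
#'
#' @param days_to_flowering positive numeric vector, in days.
#' @return character vector of classes `"E"`, `"M"`, `"L"`, `"VL"` (`NA`
#'   preserved).
#' @export
maturity_class <- function(days_to_flowering) {
  d <- days_to_flowering
  if (any(!is.na(d) & d <= 0)) stop("days to flowering must be positive")
  out <- rep(NA_character_, length(d))
  out[!is.na(d) & d <= 85] <- "E"
  out[!is.na(d) & d > 85 & d <= 105] <- "M"
  out[!is.na(d) & d > 105 & d <= 135] <- "L"
  out[!is.na(d) & d > 135] <- "VL"
  out
}

#' Grain shape class from length and width
#'
#' Length/width ratio classes: A if L/W > 3.0, B if 2.5 < L/W <= 3.0, C if
#' L/W <= 2.5 (so a ratio of exactly 3.0 is B and exactly 2.5 is C).
#'
#' @param length_mm,width_mm grain dimensions in mm (positive).
#' @return data frame with `lw_ratio` and `shape` (`NA` rows preserved).
#' @export
grain_shape_class <- function(length_mm, width_mm) {
  if (any(!is.na(width_mm) & width_mm <= 0))
    stop("grain width must be positive")
  if (any(!is.na(length_mm) & length_mm <= 0))
    stop("grain length must be positive")
  r <- length_mm / width_mm
  shape <- rep(NA_character_, length(r))
  shape[!is.na(r) & r > 3.0] <- "A"
  shape[!is.na(r) & r > 2.5 & r <= 3.0] <- "B"
  shape[!is.na(r) & r <= 2.5] <- "C"
  data.frame(lw_ratio = r, shape = shape, stringsAsFactors = FALSE)
}

#' Endosperm type from the iodine staining color
#'
#' Dark blue indicates glutinous (G) grain; brown indicates non-glutinous
#' (NG); unknown is preserved.
#'
#' @param color character vector with values `"dark-blue"`, `"brown"` or
#'   `"unknown"` (already-classified `"G"`/`"NG"` pass through).
#' @return character vector of `"G"`, `"NG"`, `"unknown"`.
#' @export
endosperm_from_iodine <- function(color) {
  out <- rep(NA_character_, length(color))
  out[color == "dark-blue" | color == "G"] <- "G"
  out[color == "brown" | color == "NG"] <- "NG"
  out[color == "unknown" | is.na(color)] <- "unknown"
  bad <- is.na(out)
  if (any(bad))
    stop("unrecognized iodine color value(s): ",
         paste(unique(color[bad]), collapse = ", "))
  out
}

#' Population characterization cross-tabulations
#'
#' Counts of region x population, ecosystem x population, maturity class x
#' population, grain shape x population and endosperm type x population,
#' with row and column totals. Admixed accessions form their own column;
#' missing metadata is counted under `"na"`.
#'
#' @param labels named per-accession population labels (e.g. from
#'   [assign_populations()]; `"admixed"` allowed).
#' @param passport passport data frame (`accession_id`, `region`,
#'   `ecosystem`, ...), optional.
#' @param phenotype phenotype data frame (`accession_id`,
#'   `days_to_flowering`, `grain_length_mm`, `grain_width_mm`, `endosperm`),
#'   optional.
#' @return named list of contingency-table matrices (traits in rows,
#'   populations in columns, with a `Total` row and column).
#' @export
characterize_populations <- function(labels, passport = NULL,
                                     phenotype = NULL) {
  acc <- names(labels)
  if (is.null(acc)) stop("labels must be named by accession id")
  pops <- c(sort(setdiff(unique(labels), "admixed")),
            if ("admixed" %in% labels) "admixed")
  pull <- function(df, col) {
    if (is.null(df) || !col %in% names(df)) return(rep(NA, length(acc)))
    df[[col]][match(acc, df$accession_id)]
  }
  xtab <- function(trait) {
    trait <- as.character(trait)
    trait[is.na(trait) | trait == "" | trait == "unknown"] <- "na"
    tl <- sort(setdiff(unique(trait), "na"))
    if ("na" %in% trait) tl <- c(tl, "na")
    tab <- matrix(0L, length(tl), length(pops), dimnames = list(tl, pops))
    for (i in seq_along(acc))
      tab[trait[i], labels[i]] <- tab[trait[i], labels[i]] + 1L
    tab <- cbind(tab, Total = rowSums(tab))
    rbind(tab, Total = colSums(tab))
  }
  out <- list()
  if (!is.null(passport)) {
    out$region <- xtab(pull(passport, "region"))
    out$ecosystem <- xtab(pull(passport, "ecosystem"))
    out$varietal_type <- xtab(pull(passport, "varietal_type"))
  }
  if (!is.null(phenotype)) {
    out$maturity <- xtab(maturity_class(pull(phenotype, "days_to_flowering")))
    sh <- grain_shape_class(pull(phenotype, "grain_length_mm"),
                            pull(phenotype, "grain_width_mm"))
    out$shape <- xtab(sh$shape)
    out$endosperm <- xtab(endosperm_from_iodine(pull(phenotype, "endosperm")))
  }
  out
}
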