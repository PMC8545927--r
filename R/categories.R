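# The 13 ICD-9-CM chapter categories used for disease-network composition
# profiles. Symptoms, injuries, poisonings, pregnancy/perinatal chapters,
# external causes (E) and factors influencing health status (V) are
# excluded before profiling. The chapter boundaries follow the standard
# ICD-9-CM chapter layout; the exact table used in the source analyses was
# not published, so edge cases at chapter boundaries may differ.

category_table <- tibble::tibble(
  lo = c(1, 140, 240, 280, 290, 320, 390, 460, 520, 580, 680, 710, 740),
  hi = c(139, 239, 279, 289, 319, 389, 459, 519, 579, 629, 709, 739, 759),
  label = c(
    "001-139 infectious and parasitic diseases",
    "140-239 neoplasms",
    "240-279 endocrine, nutritional and metabolic diseases, and immunity disorders",
    "280-289 diseases of the blood and blood-forming organs",
    "290-319 mental disorders",
    "320-389 diseases of the nervous system and the sense organs",
    "390-459 diseases of the circulatory system",
    "460-519 diseases of the respiratory system",
    "520-579 diseases of the digestive system",
    "580-629 diseases of the genitourinary system",
    "680-709 diseases of the skin and subcutaneous tissue",
    "710-739 diseases of the musculoskeletal system and connective tissue",
    "740-759 congenital anomalies"
  )
)

#' The 13 ICD-9-CM disease categories
#'
#' @return Tibble with the chapter ranges (`lo`, `hi`) and `label` of the
#'   13 categories counted in PDN composition profiles.
#' @export
disease_categories <- function() category_table

#' Assign ICD-9-CM codes to disease categories
#'
#' Maps the 3-digit root of each code into one of 13 chapter ranges;
#' codes from the excluded chapters (pregnancy 630-679, perinatal 760-779,
#' symptoms 780-799, injuries and poisonings 800-999, E-codes, V-codes)
#' are labelled `"EXCLUDED"`.
#'
#' @param codes Character vector of ICD-9-CM codes.
#' @return Character vector of category labels (or `"EXCLUDED"`).
#' @examples
#' assign_category(c("401.1", "850", "V27"))
#' @export
assign_category <- function(codes) {
  canonical <- icd_canonicalize(codes)
  root <- icd_root_number(canonical)
  idx <- findInterval(root, category_table$lo)
  ok <- !is.na(root) & idx >= 1 & root <= category_table$hi[pmax(idx, 1)]
  out <- rep("EXCLUDED", length(codes))
  out[ok] <- category_table$label[idx[ok]]
  out[is.na(canonical)] <- NA_character_
  out
}

#' Category composition profile of a disease network
#'
#' Counts, per category, the non-excluded nodes of a PDN (or of a plain
#' code vector). All 13 categories appear in the result, zero-filled.
#'
#' @param x A `pdn` object or a character vector of ICD-9-CM codes.
#' @return An object of class `category_profile`: tibble with `category`
#'   and `count`, plus a `total` attribute (number of non-excluded nodes).
#' @export
category_profile <- function(x) {
  codes <- if (inherits(x, "pdn")) x$nodes$code else icd_canonicalize(x)
  cats <- assign_category(codes)
  kept <- cats[!is.na(cats) & cats != "EXCLUDED"]
  prof <- tibble(category = category_table$label) |>
    left_join(count(tibble(category = kept), .data$category),
              by = "category") |>
    mutate(count = tidyr::replace_na(.data$n, 0L)) |>
    select("category", "count")
  structure(prof, total = length(kept), class = c("category_profile",
                                                  class(prof)))
}

#' Compare the category composition of two disease networks
#'
#' Per-category two-sample proportion test (pooled-variance z statistic,
#' two-sided, no continuity correction) of the share each category takes
#' among the non-excluded nodes of two PDNs.
#'
#' @param a,b `category_profile` objects (see [category_profile()]).
#' @param alpha Significance level (default 0.05).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   `"none"` (default) reports raw per-category p-values, `"bonferroni"`
#'   is available.
#' @return Tibble with per-category counts, proportions, `z`, `p_value`,
#'   `significant`, `direction` (`"a>b"`, `"a<b"` or `"equal"`) and an
#'   `undefined` flag for categories empty in both profiles.
#' @export
compare_profiles <- function(a, b, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(a, "category_profile"), inherits(b, "category_profile"))
  n_a <- attr(a, "total"); n_b <- attr(b, "total")
  if (n_a <= 0 || n_b <= 0) {
    abort("Both profiles must contain at least one non-excluded node.",
          class = "comorbnet_validation_error")
  }
  out <- tibble(
    category = a$category, x_a = a$count,
    x_b = b$count[match(a$category, b$category)],
    n_a = n_a, n_b = n_b
  ) |>
    mutate(
      prop_a = .data$x_a / .data$n_a,
      prop_b = .data$x_b / .data$n_b,
      pooled = (.data$x_a + .data$x_b) / (.data$n_a + .data$n_b),
      se = sqrt(.data$pooled * (1 - .data$pooled) *
                  (1 / .data$n_a + 1 / .data$n_b)),
      undefined = .data$se == 0,
      z = if_else(.data$undefined, NA_real_,
                  (.data$prop_a - .data$prop_b) / .data$se),
      p_value = if_else(.data$undefined & .data$x_a == 0 & .data$x_b == 0,
                        NA_real_, 2 * pnorm(-abs(.data$z)))
    )
  out$p_value[!out$undefined] <- stats::p.adjust(out$p_value[!out$undefined],
                                                 method = adjust)
  out |>
    mutate(
      significant = !is.na(.data$p_value) & .data$p_value < alpha,
      direction = case_when(
        .data$prop_a > .data$prop_b ~ "a>b",
        .data$prop_a < .data$prop_b ~ "a<b",
        TRUE ~ "equal"
      )
    ) |>
    select(-"pooled", -"se")
}
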