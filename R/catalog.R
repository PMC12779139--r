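#' Default outpatient tariff catalog and surgery code table
#'
#' Builds the catalog of outpatient tariff codes (with their exam category
#' and per-service cost in scaled euros) and the ICD-9-CM procedure codes
#' recognised as breast surgery. The default catalog mirrors the service mix
#' seen in regional administrative data: four biopsy variants (echo-guided
#' fine-needle, echo-guided with retroaspiration, stereotactic microbiopsy,
#' stereotactic with retroaspiration) whose costs span two orders of
#' magnitude, mono/bilateral mammography plus tomosynthesis, mono/bilateral
#' ultrasound, and first/follow-up breast visit codes.
#'
#' The wide spread of biopsy costs, with the cheap fine-needle variant the
#' most common, is what makes per-patient biopsy cost distributions
#' right-skewed (mean well above median).
#'
#' @param scale multiplier applied to every cost (scaled standardized euros
#'   are defined up to an undisclosed regional factor; default 1).
#' @return An object of class `tariff_catalog`: a list with `entries` (tibble
#'   with columns `tariff_code`, `category`, `description`, `cost`, `weight`)
#'   and `surgery_codes` (tibble with `procedure_code`, `surgery_type`).
#' @export
#' @examples
#' cat <- default_catalog()
#' table(cat$entries$category)
default_catalog <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale >= 0)
  entries <- tribble(
    ~tariff_code, ~category,      ~description,                                      ~cost, ~weight,
    "B-FNA",      "biopsy",       "echo-guided fine-needle breast biopsy",            0.71,    0.55,
    "B-ECR",      "biopsy",       "echo-guided breast biopsy with retroaspiration",   8.40,    0.25,
    "B-SMB",      "biopsy",       "stereotactic breast microbiopsy",                 45.00,    0.12,
    "B-SRA",      "biopsy",       "stereotactic breast biopsy with retroaspiration", 62.00,    0.08,
    "M-MONO",     "mammography",  "monolateral mammography",                          2.36,    0.55,
    "M-BIL",      "mammography",  "bilateral mammography",                            4.10,    0.35,
    "M-TOMO",     "mammography",  "tomosynthesis (three-dimensional mammogram)",      9.80,    0.10,
    "U-MONO",     "ultrasound",   "monolateral breast ultrasound",                    1.70,    0.60,
    "U-BIL",      "ultrasound",   "bilateral breast ultrasound",                      3.20,    0.40,
    "V-FIRST",    "visit",        "first breast visit",                               5.43,    0.70,
    "V-FUP",      "visit",        "follow-up breast visit",                           4.20,    0.30
  )
  entries$cost <- entries$cost * scale
  surgery_codes <- tribble(
    ~procedure_code, ~surgery_type,
    "85.21", "BCT",
    "85.22", "BCT",
    "85.23", "BCT",
    "85.33", "reconstruction",
    "85.34", "reconstruction",
    "85.35", "reconstruction",
    "85.36", "reconstruction",
    "85.41", "mastectomy",
    "85.42", "mastectomy",
    "85.43", "mastectomy",
    "85.44", "mastectomy"
  )
  new_tariff_catalog(entries, surgery_codes)
}

new_tariff_catalog <- function(entries, surgery_codes) {
  if (anyDuplicated(entries$tariff_code) > 0) {
    abort("tariff_catalog: tariff codes must be unique")
  }
  if (!all(exam_categories() %in% entries$category)) {
    abort("tariff_catalog: every exam category must have at least one code")
  }
  if (any(entries$cost < 0)) {
    abort("tariff_catalog: costs must be nonnegative")
  }
  structure(list(entries = entries, surgery_codes = surgery_codes),
            class = "tariff_catalog")
}

#' @export
print.tariff_catalog <- function(x, ...) {
  cat("<tariff_catalog> ", nrow(x$entries), " tariff codes (",
      paste(sort(unique(x$entries$category)), collapse = ", "), "); ",
      nrow(x$surgery_codes), " surgery procedure codes\n", sep = "")
  invisible(x)
}

# codes of one category, in catalog order
catalog_codes <- function(catalog, category) {
  catalog$entries$tariff_code[catalog$entries$category == category]
}

# named vector tariff_code -> category
catalog_category_map <- function(catalog) {
  setNames(catalog$entries$category, catalog$entries$tariff_code)
}

# draw one tariff row for a category using the catalog sampling weights
sample_tariff <- function(catalog, category) {
  e <- catalog$entries[catalog$entries$category == category, ]
  i <- sample.int(nrow(e), 1L, prob = e$weight)
  e[i, ]
}
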