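# Published group-level summary statistics (median, arithmetic mean,
# min-max range, all ppb) of the volatile compounds selected by the final
# discriminant models, for controls and each patient group. These numbers
# parameterize the synthetic cohort generator.

.control_summary <- function() {
  tab <- rbind(
    c("acetic_acid",    1124.0,  1336.8,  402.5,  3742.7),
    c("ammonia",         160.6,   602.3,   52.1,  6375.2),
    c("M43",            1193.0,  1430.5,  606.5,  6938.6),
    c("acetaldehyde",    818.0,  1976.1,  202.2,  9423.5),
    c("M48",               6.8,     7.8,    3.0,    17.3),
    c("M62",               8.7,     9.2,    2.7,    19.9),
    c("M67",              34.4,    35.9,   12.5,    75.5),
    c("pentane",          64.3,    64.5,   29.5,   130.2),
    c("M93",              31.9,    35.7,    6.3,   299.6),
    c("M98",              58.4,    67.1,   23.2,   256.9),
    c("M103",              4.2,     7.1,    1.3,    31.7),
    c("butadiene_1_3",    10.9,    11.8,    3.2,    25.6),
    c("M74",              23.4,    31.6,    9.7,    90.7),
    c("M105",              9.4,     9.9,    3.7,    25.9),
    c("M121",              3.7,     5.1,    1.1,    23.5),
    c("N2O",            6438.0,  6311.9, 2323.5, 11934.3),
    c("HNO2",             21.3,    25.6,   10.1,    70.7),
    c("M19",             350.4,   623.2,   84.3,  1953.8),
    c("M33",              46.1,    51.8,    8.0,   200.6),
    c("M75",               6.7,    13.5,    1.7,   101.4),
    c("M91",               6.7,     9.0,    2.2,    35.3),
    c("M106",              9.4,    11.2,    3.9,    37.6),
    c("M120",              3.2,     3.9,    0.6,    19.4))
  data.frame(compound = tab[, 1],
             median = as.numeric(tab[, 2]),
             mean = as.numeric(tab[, 3]),
             range_min = as.numeric(tab[, 4]),
             range_max = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
}

.case_summary <- function(contrast) {
  tab <- switch(contrast,
    lung_adk = rbind(
      c("acetic_acid",   1872.8, 1855.5,  376.1,  3999.2),
      c("ammonia",        173.6,  171.1,   32.6,   384.4),
      c("M43",            927.9, 1071.5,  284.5,  2773.8),
      c("acetaldehyde",   580.2, 1901.1,  105.5, 11089.2),
      c("M48",              6.3,   11.6,    1.6,   199.3),
      c("M62",              8.9,   10.5,    1.9,    31.1),
      c("M67",             27.2,   28.6,    4.0,    52.1),
      c("pentane",         78.8,   85.6,   37.4,   188.0),
      c("M93",             24.2,   26.9,    4.4,    92.5),
      c("M98",             62.6,   65.0,   26.3,   135.4),
      c("M103",             6.1,   14.4,    0.6,   131.6)),
    lung_sqcc = rbind(
      c("acetic_acid",   2119.7, 2627.4,  478.9,  8398.6),
      c("ammonia",        219.9,  276.2,   42.7,   947.4),
      c("M43",           1260.8, 1599.1,  350.6,  7699.2),
      c("acetaldehyde",  1362.2, 2120.2,  116.7,  9456.8),
      c("M48",              6.4,    8.1,    2.0,    26.8),
      c("butadiene_1_3",   13.6,   27.6,    3.2,   255.1),
      c("M74",             37.8,   58.9,    9.8,   231.8),
      c("M105",            11.1,   15.2,    5.3,    57.3),
      c("M121",             4.5,    5.1,    1.5,    10.2)),
    colon_adk = rbind(
      c("N2O",           7306.1, 7183.9, 3985.6, 11263.5),
      c("HNO2",            23.2,   24.3,   10.0,    58.5),
      c("acetic_acid",   1015.1, 1155.9,  433.4,  2302.8),
      c("M19",            590.0,  708.7,  102.8,  3443.9),
      c("M33",             55.5,   81.1,    6.5,   296.8),
      c("M43",           1650.7, 1906.7,  715.5,  5582.1),
      c("butadiene_1_3",   12.3,   16.3,    1.8,   177.3),
      c("M67",             39.1,   42.9,   16.5,   117.7),
      c("M74",             17.2,   46.9,    5.8,   460.2),
      c("M75",              3.8,    8.7,    0.6,    53.0),
      c("M91",             13.3,   14.9,    0.6,    38.9),
      c("M106",             8.0,   20.3,    3.0,   116.8),
      c("M120",             2.1,    3.2,    0.2,    12.1)),
    stop("unknown contrast: ", contrast))
  data.frame(compound = tab[, 1],
             median = as.numeric(tab[, 2]),
             mean = as.numeric(tab[, 3]),
             range_min = as.numeric(tab[, 4]),
             range_max = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
}

#' Published summary statistics of the model-selected compounds
#'
#' Median, arithmetic mean and min-max range (ppb) of the volatile
#' compounds retained by the final discriminant models, per group. These
#' tables parameterize [default_cohort_spec()].
#'
#' @param group One of `"control"`, `"lung_adk"`, `"lung_sqcc"`,
#'   `"colon_adk"`.
#' @return A data frame with columns `compound`, `median`, `mean`,
#'   `range_min`, `range_max`.
#' @export
compound_summary_table <- function(group = c("control", "lung_adk",
                                             "lung_sqcc", "colon_adk")) {
  group <- match.arg(group)
  if (group == "control") .control_summary() else .case_summary(group)
}

# Cohort structure: group sizes, male counts and printed age ranges
# (union of the per-sex ranges).
.group_structure <- function() {
  data.frame(group = c("control", "lung_adk", "lung_sqcc", "colon_adk"),
             n = c(45L, 36L, 25L, 52L),
             n_male = c(30L, 21L, 13L, 24L),
             age_min = c(43, 45, 55, 43),
             age_max = c(87, 85, 86, 89),
             stringsAsFactors = FALSE)
}
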