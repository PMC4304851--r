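#' Canonical county variable registry
#'
#' The registry fixes the canonical lowercase snake_case column names the
#' pipeline works with, together with each variable's role, units, and the
#' unweighted mean/sd and non-missing count (out of 259 quality-controlled
#' counties) that the synthetic generator uses as default marginals. Means
#' and sds follow the compiled multi-source county dataset this pipeline is
#' designed for; `NA` marginals mark structural columns that are never drawn
#' from the copula.
#'
#' @return A tibble with columns `variable`, `role`
#'   (`id`/`state`/`population`/`predictor`/`outcome`/`qc`), `mean`, `sd`,
#'   `n_nonmissing`, `units`.
#' @export
county_registry <- function() {
  tibble::tribble(
    ~variable,                  ~role,         ~mean,   ~sd,   ~n_nonmissing, ~units,
    "county_id",                "id",          NA,      NA,    NA,  "FIPS code",
    "state",                    "state",       NA,      NA,    NA,  "2-letter code",
    "population",               "population",  NA,      NA,    NA,  "persons",
    "black",                    "predictor",   1.9,     2.6,   259, "%",
    "education",                "predictor",   24,      10,    259, "% adults with bachelor's",
    "income",                   "predictor",   49,      11,    259, "thousand USD",
    "metro",                    "predictor",   0.43,    0.5,   259, "binary",
    "obesity",                  "predictor",   21,      3.5,   259, "% prevalence",
    "white",                    "predictor",   86,      11,    259, "%",
    "elevation",                "predictor",   0.97,    0.74,  259, "km",
    "diabetes",                 "predictor",   6.6,     1,     259, "% age-adjusted prevalence",
    "drinking",                 "predictor",   15,      3.8,   244, "% binge drinking",
    "smoking_female",           "predictor",   41,      6.8,   258, "% smoked in lifetime",
    "male",                     "predictor",   50,      1.6,   259, "%",
    "mammogram",                "predictor",   64,      6.2,   259, "% within two years",
    "meat",                     "predictor",   67,      12,    259, "lbs/household/yr",
    "other_cancer_breast",      "predictor",   273,     33,    259, "incidence per 100k",
    "other_cancer_colorectal",  "predictor",   396,     42,    258, "incidence per 100k",
    "other_cancer_lung",        "predictor",   382,     36,    255, "incidence per 100k",
    "other_cancer_prostate",    "predictor",   352,     48,    259, "incidence per 100k",
    "smoking",                  "predictor",   47,      5.8,   258, "% smoked in lifetime",
    "smoking_male",             "predictor",   53,      5.5,   258, "% smoked in lifetime",
    "particulate",              "predictor",   10,      1.8,   259, "ug/m3",
    "radon",                    "predictor",   1.7,     1,     258, "pCi/L",
    "uvb",                      "predictor",   1072,    239,   259, "kJ/m2",
    "sunlight",                 "predictor",   17060,   1939,  259, "kJ/m3",
    "precipitation",            "predictor",   1.9,     1.5,   259, "mm/day",
    "high_temp",                "predictor",   16,      4.6,   259, "deg C",
    "diurnal_temp",             "predictor",   9.5,     1.6,   259, "deg C",
    "immigration",              "qc",          16,      8,     259, "% five-year movers",
    "native_american",          "qc",          4,       6,     259, "%",
    "lung",                     "outcome",     56.8,    14.4,  257, "incidence per 100k",
    "breast",                   "outcome",     119.3,   16.7,  259, "incidence per 100k",
    "colorectal",               "outcome",     41.9,    6.0,   259, "incidence per 100k",
    "prostate",                 "outcome",     148.6,   23.9,  259, "incidence per 100k",
    "all_site",                 "outcome",     NA,      NA,    NA,  "incidence per 100k",
    "lung_male",                "outcome",     70,      18,    259, "incidence per 100k",
    "lung_female",              "outcome",     48,      13,    259, "incidence per 100k",
    "lung_under65",             "outcome",     22,      6,     259, "incidence per 100k",
    "lung_65plus",              "outcome",     330,     80,    259, "incidence per 100k",
  )
}

#' Cancer-specific covariate sets
#'
#' Covariates included alongside the exposure for each cancer: 11 for lung,
#' 10 for breast, 12 for colorectal and 8 for prostate. Six demographic
#' covariates (metro, white, black, education, income, obesity) plus the
#' other-cancer incidence are shared by all four; the rest are
#' cancer-specific risk factors. `env` lists the seven environmental
#' variables evaluated as exposure replacements in the substitution analysis.
#'
#' @return Named list of character vectors (the exposure itself, by default
#'   `elevation`, is not listed; it is forced separately).
#' @export
covariate_sets <- function() {
  shared <- c("metro", "white", "black", "education", "income", "obesity")
  list(
    lung = c(shared, "other_cancer_lung", "smoking", "radon", "particulate",
             "male"),
    breast = c(shared, "other_cancer_breast", "smoking_female", "mammogram",
               "drinking"),
    colorectal = c(shared, "other_cancer_colorectal", "smoking", "drinking",
                   "diabetes", "meat", "male"),
    prostate = c(shared, "other_cancer_prostate", "meat"),
    env = c("radon", "particulate", "uvb", "sunlight", "precipitation",
            "high_temp", "diurnal_temp")
  )
}

# Eight demographic/health covariates used by the all-site divergence
# diagnostic (exposure deliberately excluded to avoid opportunistic
# threshold selection).
diagnostic_covariates <- function() {
  c("metro", "white", "black", "education", "income", "obesity", "male",
    "smoking")
}

western_states <- function() {
  c("AZ", "CA", "CO", "ID", "MT", "NV", "NM", "OR", "UT", "WA", "WY")
}
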