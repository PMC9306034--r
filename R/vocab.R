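#' The ten-variable identifier key
#'
#' Returns the names of the ten matching variables shared by the survey and
#' admissions datasets: age, sex, residence district, admission source,
#' month of admission, month of discharge, admission specialty, discharge
#' specialty, discharge hospital and length of stay. Deterministic linkage
#' requires exact equality on every one of them.
#'
#' @return Character vector of the ten key column names.
#' @export
identifier_keys <- function() {
  c("age", "sex", "residence_district", "admission_source",
    "admission_month", "discharge_month", "admission_specialty",
    "discharge_specialty", "discharge_hospital", "length_of_stay")
}

# Canonical categorical vocabularies. Everything is lower-case snake_case
# after standardization; the generator only ever emits canonical values.

vocab_sex <- c("male", "female")

vocab_admission_source <- c("ae", "opd", "other")

vocab_discharge_destination <- c("home", "other")

# 18 Hong Kong districts
vocab_district <- c(
  "central_western", "eastern", "southern", "wan_chai",
  "kowloon_city", "kwun_tong", "sham_shui_po", "wong_tai_sin",
  "yau_tsim_mong", "islands", "kwai_tsing", "north", "sai_kung",
  "sha_tin", "tai_po", "tsuen_wan", "tuen_mun", "yuen_long")

vocab_hospital <- paste0("hospital_", 1:7)

# Specialty codes and their four-way analysis grouping. Medicine covers the
# cardiac care unit, geriatrics, infectious disease and general medicine;
# eight low-volume specialties are pooled as "others".
default_specialty_groups <- c(
  general_medicine       = "medicine",
  geriatrics             = "medicine",
  cardiac_care           = "medicine",
  infectious_disease     = "medicine",
  general_surgery        = "surgery",
  oncology               = "oncology",
  cardiothoracic_surgery = "others",
  emergency_medicine     = "others",
  ent                    = "others",
  gynaecology            = "others",
  neurosurgery           = "others",
  ophthalmology          = "others",
  orthopaedics           = "others",
  rehabilitation         = "others")

vocab_specialty <- names(default_specialty_groups)

#' Default specialty-to-group dictionary
#'
#' Maps each discharge/admission specialty code to one of the four analysis
#' groups (`medicine`, `surgery`, `oncology`, `others`). Medicine includes
#' the cardiac care unit, geriatrics, infectious disease and general
#' medicine; the eight small specialties (cardiothoracic surgery, emergency
#' medicine, ENT, gynaecology, neurosurgery, ophthalmology, orthopaedics,
#' rehabilitation) are pooled as "others".
#'
#' @return Named character vector: names are specialty codes, values groups.
#' @export
specialty_dictionary <- function() {
  default_specialty_groups
}

# Column dictionaries for the two source tables
survey_columns <- function() {
  c("survey_id", identifier_keys(), "quality_rating", "experience_score")
}

admission_columns <- function() {
  c("pseudo_id", identifier_keys(), "cssa_flag", "discharge_destination",
    "diagnosis_code", "procedure_code")
}
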