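#' Controlled vocabularies
#'
#' Token sets used throughout the survey data model. Readers accept either
#' the full word or the single/double-letter field abbreviation commonly used
#' in printed ethnobotanical tables (e.g. `H` for Herb, `Wp` for WholePlant,
#' `N`/`E` for Native/Exotic); everything is normalized internally to the
#' full-word form.
#'
#' @name vocab
#' @keywords internal
NULL

.cats <- c("GAS", "CAR", "DER", "GYN", "NER", "PAR", "CAN", "RES",
           "SKE", "MET", "ETH", "EY", "ENT", "FVR", "IB")

.cat_labels <- c(
  GAS = "Gastrointestinal problems",
  CAR = "Cardiovascular problems",
  DER = "Dermatological disorders",
  GYN = "Gynecological problems",
  NER = "Nervous system disorders",
  PAR = "Parasitic problems",
  CAN = "Cancer",
  RES = "Respiratory complaints",
  SKE = "Skeleto-muscular system disorders",
  MET = "Metabolic syndromes",
  ETH = "Ethnoveterinary ailments",
  EY  = "Energy yielding",
  ENT = "Eyes, ears and nose problems",
  FVR = "Fever issues",
  IB  = "Insect bites")

.life_forms <- c("Herb", "Shrub", "Tree", "Liana", "Parasite")

# Stem and Latex appear in field tables alongside the classical part codes.
.plant_parts <- c("Bark", "Bulb", "Flower", "Leaf", "Fruit", "Seed",
                  "Rhizome", "Root", "Shoot", "Stem", "Inflorescence",
                  "Tuber", "WholePlant", "Latex")

.preparations <- c("Powder", "JuiceExtract", "Paste", "Decoction", "Chew")

.routes <- c("Oral", "Topical", "Bath", "SmokeInhalation")

.nativities <- c("Native", "Exotic")

.genders <- c("F", "M")

.communities <- c("Dard", "Gujjar", "Kashmiri")

# ordered: Illiterate < Primary < ... < Postgraduate
.educations <- c("Illiterate", "Primary", "Middle", "Matric",
                 "SeniorSecondary", "Graduate", "Postgraduate")

# age bins used for the age_category contingency factor
.age_breaks <- c(-Inf, 30, 40, 50, 60, 70, 80)
.age_labels <- c("<=30", "31-40", "41-50", "51-60", "61-70", "71-80")

# dialect tables: lowercased alias -> canonical token
.aliases <- list(
  life_form = c(h = "Herb", s = "Shrub", t = "Tree", l = "Liana",
                p = "Parasite"),
  plant_part = c(b = "Bark", bb = "Bulb", fl = "Flower", lv = "Leaf",
                 fr = "Fruit", se = "Seed", rh = "Rhizome", rt = "Root",
                 sh = "Shoot", st = "Stem", inf = "Inflorescence",
                 tu = "Tuber", wp = "WholePlant", lt = "Latex"),
  preparation = c("juice/extract" = "JuiceExtract",
                  "juice extract" = "JuiceExtract",
                  "juiceextract" = "JuiceExtract",
                  "chew/roasted" = "Chew", "chew//roasted" = "Chew"),
  nativity = c(n = "Native", e = "Exotic"),
  gender = c(f = "F", m = "M", female = "F", male = "M"),
  education = c("senior secondary" = "SeniorSecondary",
                "seniorsecondary" = "SeniorSecondary",
                "matriculation" = "Matric",
                "post graduate" = "Postgraduate",
                "postgraduate" = "Postgraduate"))

#' Normalize a vector of vocabulary tokens
#'
#' Trims whitespace, resolves field abbreviations, and matches the canonical
#' token case-insensitively. Unknown tokens raise an error naming them.
#'
#' @param x character vector of raw tokens.
#' @param vocab character vector of canonical tokens.
#' @param aliases optional named character vector, lowercased alias -> token.
#' @param field label used in error messages.
#' @return character vector of canonical tokens.
#' @keywords internal
normalize_token <- function(x, vocab, aliases = NULL, field = "value") {
  raw <- trimws(as.character(x))
  key <- tolower(raw)
  out <- vocab[match(key, tolower(vocab))]
  if (!is.null(aliases)) {
    hit <- !is.na(match(key, names(aliases)))
    out[hit] <- aliases[key[hit]]
  }
  bad <- is.na(out) & !is.na(raw) & nzchar(raw)
  if (any(bad)) {
    stop(sprintf("unknown %s token(s): %s", field,
                 paste(unique(raw[bad]), collapse = ", ")), call. = FALSE)
  }
  out[is.na(raw) | !nzchar(raw)] <- NA_character_
  out
}

#' Disease category codes
#'
#' The fifteen ailment categories into which all recorded biomedical
#' ailments are binned before computing the informant consensus factor.
#'
#' @return data.frame with columns `category` and `label`.
#' @examples
#' disease_categories()
#' @export
disease_categories <- function() {
  data.frame(category = .cats, label = unname(.cat_labels[.cats]),
             stringsAsFactors = FALSE)
}
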