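#' Default substance lexicon for the synthetic generator
#'
#' Common substances implicated in overdose surveillance. The test-year
#' generator of [simulate_study()] adds a novel substance absent from this
#' list to emulate the year-split difficulty: drugs that emerge in the test
#' year were never seen in training data.
#'
#' @return Character vector of uppercase substance names.
#' @export
default_drug_lexicon <- function() {
  c("HEROIN", "FENTANYL", "COCAINE", "METHAMPHETAMINE", "OXYCODONE",
    "ALPRAZOLAM", "ETHANOL")
}

# --- template tables ----------------------------------------------------
# {D1}/{D2} are substituted with sampled substances. Overdose certificates
# mimic the terse shape of real certifier text: a populated immediate
# cause, usually blank due-to lines, and an injury description. One
# template ("COMPLICATIONS OF {D1} USE") carries no generic overdose
# keyword, so keyword lists miss it whenever the substance itself is not
# on the list.

od_templates <- function() {
  list(
    list(a = "ACUTE {D1} TOXICITY", b = "", inj = "ACCIDENTAL OVERDOSE", w = 0.22),
    list(a = "{D1} OVERDOSE", b = "", inj = "ACCIDENTAL DRUG OVERDOSE", w = 0.18),
    list(a = "MIXED DRUG INTOXICATION", b = "{D1} AND {D2} USE",
         inj = "SUBSTANCE ABUSE", w = 0.14),
    list(a = "COMBINED {D1} AND {D2} TOXICITY", b = "",
         inj = "ACCIDENTAL OVERDOSE", w = 0.14),
    list(a = "ACUTE INTOXICATION", b = "COMBINED EFFECTS OF {D1} AND {D2}",
         inj = "DRUG INGESTION", w = 0.10),
    list(a = "COMPLICATIONS OF {D1} USE", b = "", inj = "", w = 0.12),
    list(a = "ANOXIC BRAIN INJURY", b = "{D1} OVERDOSE",
         inj = "ACCIDENTAL OVERDOSE", w = 0.10)
  )
}

non_od_templates <- function() {
  list(
    list(a = "ACUTE MYOCARDIAL INFARCTION", b = "CORONARY ARTERY DISEASE",
         inj = "", ucod = "I21", w = 0.208),
    list(a = "CONGESTIVE HEART FAILURE",
         b = "HYPERTENSIVE CARDIOVASCULAR DISEASE", inj = "", ucod = "I50",
         w = 0.13),
    list(a = "METASTATIC LUNG CANCER", b = "", inj = "", ucod = "C34",
         w = 0.12),
    list(a = "CHRONIC OBSTRUCTIVE PULMONARY DISEASE", b = "", inj = "",
         ucod = "J44", w = 0.11),
    list(a = "CEREBROVASCULAR ACCIDENT", b = "", inj = "", ucod = "I64",
         w = 0.09),
    list(a = "SEPSIS", b = "PNEUMONIA", inj = "", ucod = "A41", w = 0.09),
    list(a = "ALZHEIMERS DEMENTIA", b = "", inj = "", ucod = "G30",
         w = 0.08),
    list(a = "END STAGE RENAL DISEASE", b = "DIABETES MELLITUS", inj = "",
         ucod = "E11", w = 0.06),
    list(a = "ALCOHOLIC CIRRHOSIS OF LIVER", b = "CHRONIC ALCOHOL ABUSE",
         inj = "", ucod = "K70", w = 0.04),
    list(a = "BLUNT FORCE INJURIES OF HEAD AND TORSO", b = "",
         inj = "DRIVER IN MOTOR VEHICLE COLLISION", ucod = "V43",
         w = 0.04),
    list(a = "GUNSHOT WOUND OF HEAD", b = "",
         inj = "SHOT SELF WITH HANDGUN", ucod = "X74", w = 0.02),
    list(a = "ENVIRONMENTAL HYPOTHERMIA", b = "ACUTE ETHANOL INTOXICATION",
         inj = "FOUND OUTDOORS IN COLD WEATHER", ucod = "X31", w = 0.002),
    list(a = "ASPHYXIA", b = "", inj = "HANGING", ucod = "X70", w = 0.01)
  )
}

benign_scc <- function() {
  c("", "", "", "DIABETES MELLITUS", "OBESITY", "TOBACCO USE",
    "HYPERTENSION", "ATRIAL FIBRILLATION",
    "HYPERTENSIVE CARDIOVASCULAR DISEASE, OBESITY")
}

confounder_scc <- function() {
  c("HISTORY OF DRUG OVERDOSE", "PREVIOUS {D1} OVERDOSE", "DRUG OVERDOSE",
    "REMOTE DRUG OVERDOSE", "{D1} ABUSE", "HISTORY OF SUBSTANCE ABUSE",
    "CHRONIC SUBSTANCE ABUSE")
}

abbrev_map <- function() {
  c(OVERDOSE = "OD", INTOXICATION = "INTOX", ACCIDENTAL = "ACC",
    HYPERTENSIVE = "HTN", DISEASE = "DZ")
}

fill_drugs <- function(s, lexicon) {
  if (grepl("{D1}", s, fixed = TRUE)) {
    s <- sub("{D1}", sample(lexicon, 1L), s, fixed = TRUE)
  }
  if (grepl("{D2}", s, fixed = TRUE)) {
    s <- sub("{D2}", sample(lexicon, 1L), s, fixed = TRUE)
  }
  s
}

# certifier-noise model: drop a word, duplicate a word, or abbreviate
apply_noise <- function(text) {
  toks <- strsplit(text, " ", fixed = TRUE)[[1]]
  if (length(toks) < 2L) return(text)
  op <- sample(c("drop", "dup", "abbrev"), 1L)
  if (op == "abbrev") {
    hit <- which(toks %in% names(abbrev_map()))
    if (length(hit)) {
      i <- if (length(hit) == 1L) hit else sample(hit, 1L)
      toks[i] <- abbrev_map()[[toks[i]]]
      return(paste(toks, collapse = " "))
    }
    op <- "drop"
  }
  i <- sample(length(toks), 1L)
  if (op == "drop") toks <- toks[-i] else toks <- append(toks, toks[i], i)
  paste(toks, collapse = " ")
}

sample_od_ucod <- function() {
  codes <- overdose_ucod_codes()
  w <- c(rep(0.16, 5), rep(0.016, 5), 0.01, rep(0.022, 5))
  code <- sample(codes, 1L, prob = w)
  if (stats::runif(1) < 0.7) code <- paste0(code, sample(0:9, 1L))
  code
}

#' Generate synthetic labeled death certificates
#'
#' Emulates the statistical structure the classification method assumes:
#' terse, fully capitalized certifier text; roughly 3% overdose prevalence;
#' overdose records drawn from overdose cause/injury templates with an
#' underlying-cause code sampled from the overdose ICD-10 ranges; non-
#' overdose records drawn from natural- and external-cause templates with
#' matching non-overdose codes. A `scc_confounder_rate` fraction of
#' non-overdose records carry overdose-history phrases in the significant-
#' conditions section only — the documented failure mode of including SCC
#' text in the feature space. Labels always agree with
#' [label_from_ucod()] applied to the generated code. Output is
#' deterministic given `seed`.
#'
#' @param n Number of certificates.
#' @param od_prevalence Probability a record is an overdose death
#'   (default 0.03).
#' @param scc_confounder_rate Probability a non-overdose record carries an
#'   overdose-history phrase in SCC (default 0.05).
#' @param drug_lexicon Uppercase substance names to draw from.
#' @param template_noise Per-record probability of a certifier-noise
#'   mutation (word drop, duplication, or abbreviation; default 0.05).
#' @param seed Integer seed.
#' @return Certificate data frame (see [read_certificates()]) with `ucod`
#'   and `label` populated.
#' @export
simulate_certificates <- function(n, od_prevalence = 0.03,
                                  scc_confounder_rate = 0.05,
                                  drug_lexicon = default_drug_lexicon(),
                                  template_noise = 0.05, seed = 1L) {
  stopifnot(n >= 1, od_prevalence >= 0, od_prevalence <= 1,
            scc_confounder_rate >= 0, scc_confounder_rate <= 1,
            template_noise >= 0, template_noise <= 1,
            length(drug_lexicon) >= 1)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))

  is_od <- stats::runif(n) < od_prevalence
  odt <- od_templates(); nodt <- non_od_templates()
  od_w <- vapply(odt, `[[`, 0, "w"); nod_w <- vapply(nodt, `[[`, 0, "w")

  rec <- function(i) {
    if (is_od[i]) {
      tpl <- odt[[sample(length(odt), 1L, prob = od_w)]]
      cause_a <- fill_drugs(tpl$a, drug_lexicon)
      cause_b <- fill_drugs(tpl$b, drug_lexicon)
      inj <- tpl$inj
      scc <- sample(c("", "", benign_scc()[-(1:3)]), 1L)
      ucod <- sample_od_ucod()
    } else {
      tpl <- nodt[[sample(length(nodt), 1L, prob = nod_w)]]
      cause_a <- tpl$a; cause_b <- tpl$b; inj <- tpl$inj
      scc <- if (stats::runif(1) < scc_confounder_rate) {
        fill_drugs(sample(confounder_scc(), 1L), drug_lexicon)
      } else {
        sample(benign_scc(), 1L)
      }
      ucod <- tpl$ucod
      if (stats::runif(1) < 0.6) ucod <- paste0(ucod, sample(0:9, 1L))
    }
    if (stats::runif(1) < template_noise) {
      if (nzchar(inj) && stats::runif(1) < 0.5) {
        inj <- apply_noise(inj)
      } else {
        cause_a <- apply_noise(cause_a)
      }
    }
    list(cause_a = cause_a, cause_b = cause_b, scc = scc,
         injury_desc = inj, ucod = ucod)
  }
  rows <- lapply(seq_len(n), rec)
  out <- data.frame(
    id = sprintf("DC%06d", seq_len(n)),
    cause_a = vapply(rows, `[[`, "", "cause_a"),
    cause_b = vapply(rows, `[[`, "", "cause_b"),
    cause_c = character(n),
    cause_d = character(n),
    scc = vapply(rows, `[[`, "", "scc"),
    injury_desc = vapply(rows, `[[`, "", "injury_desc"),
    ucod = vapply(rows, `[[`, "", "ucod"),
    stringsAsFactors = FALSE)
  out$label <- label_from_ucod(out$ucod)
  stopifnot(identical(out$label, is_od))
  out
}

#' Generate a train-year / test-year pair of synthetic corpora
#'
#' Mirrors the deployment design: a model is trained on one calendar year
#' and deployed on the next. The test year draws substances from the train
#' lexicon plus `novel_drug`, a substance never seen in training, which
#' degrades both the learned model (its name is an unseen token) and —
#' more severely — any keyword list that does not contain it.
#'
#' @param n_train,n_test Corpus sizes (defaults 5000 / 2000).
#' @param seed Integer seed; the test year uses `seed + 1`.
#' @param novel_drug Substance added to the test-year lexicon only
#'   (default `"CARFENTANIL"`).
#' @param drug_lexicon Train-year substance lexicon.
#' @param ... Passed on to [simulate_certificates()].
#' @return List with elements `train` and `test`.
#' @export
simulate_study <- function(n_train = 5000L, n_test = 2000L, seed = 1L,
                           novel_drug = "CARFENTANIL",
                           drug_lexicon = default_drug_lexicon(), ...) {
  seed <- as.integer(seed)
  list(
    train = simulate_certificates(n_train, seed = seed,
                                  drug_lexicon = drug_lexicon, ...),
    test = simulate_certificates(
      n_test, seed = seed + 1L,
      drug_lexicon = c(drug_lexicon, novel_drug), ...)
  )
}
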