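#' Default 104-odorant human-emanation panel
#'
#' The panel emulates the composition of a 104-odorant screen of human skin
#' volatiles drawn from 11 chemical classes (carboxylic acids the largest
#' group at 21 members, aldehydes C3-C12, alcohols, ketones,
#' aromatics/aliphatics, halides, heterocyclics, amines, esters, sulfides,
#' ureas). Named members include every odorant that matters downstream
#' (nonanal, octanal, decanal, the 2-hexen-1-ol stereoisomer pair, the
#' amines, sulcatone, the long-chain E2 ligands); fillers complete each
#' class to its size.
#'
#' @return A data.frame with columns `odorant` and `class` (104 rows).
#' @export
#' @examples
#' table(default_odorant_panel()$class)
default_odorant_panel <- function() {
  p <- list(
    carboxylic_acid = c(
      "acrylic acid", "acetic acid", "propanoic acid", "butanoic acid",
      "pentanoic acid", "methylvaleric acid", "hexanoic acid",
      "heptanoic acid", "octanoic acid", "nonanoic acid", "decanoic acid",
      "undecanoic acid", "lauric acid", "tridecanoic acid",
      "N-pentadecanoic acid", "pimelic acid", "adipic acid",
      "benzoic acid", "4-hydroxybenzoic acid", "oleic acid",
      "palmitic acid"),
    aldehyde = c(
      "propanal", "butanal", "pentanal", "hexanal", "heptanal", "octanal",
      "nonanal", "decanal", "undecanal", "dodecanal", "trans-2-hexenal"),
    alcohol = c(
      "cis-2-hexen-1-ol", "trans-2-hexen-1-ol", "1-hexanol", "1-heptanol",
      "1-octanol", "1-octen-3-ol", "2-ethyl-1-hexanol", "1-nonanol",
      "1-decanol", "benzyl alcohol", "2-phenylethanol", "geraniol",
      "linalool", "isopropanol"),
    ketone = c(
      "2-butanone", "2-pentanone", "3-pentanone", "2-hexanone",
      "2-heptanone", "2-decanone", "sulcatone", "acetophenone"),
    aromatic_aliphatic = c(
      "toluene", "ethylbenzene", "propylbenzene", "styrene", "phenol",
      "p-cresol", "limonene", "decane", "dodecane", "pentadecane",
      "hexadecane", "octadecane", "1-tetradecene", "1-hexadecene",
      "squalene"),
    halide = c(
      "1-chlorohexane", "1-chloroheptane", "1-chlorooctane",
      "1-chlorodecane", "1-chlorododecane", "1-chlorotetradecane",
      "1-chlorohexadecane", "lauroyl chloride"),
    heterocyclic = c(
      "1-methylpiperazine", "thiazolidine", "methylpyrazine",
      "2-methylindole", "indole", "pyridine", "piperidine",
      "piperidinemethanamine", "furfural", "2-acetylthiazole"),
    amine = c("ammonia", "propylamine", "butylamine"),
    ester = c(
      "methyl tridecanoate", "ethyl acetate", "ethyl hexanoate",
      "methyl octanoate", "ethyl decanoate", "methyl laurate",
      "isopropyl myristate", "benzyl acetate"),
    sulfide = c("dimethyl sulfide", "dimethyl disulfide",
                "dimethyl trisulfide"),
    urea = c("urea", "ethylurea", "methylurea")
  )
  out <- data.frame(
    odorant = unlist(p, use.names = FALSE),
    class = rep(names(p), lengths(p)),
    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 104L, !anyDuplicated(out$odorant),
            all(out$class %in% odorant_classes()))
  out
}

#' Default sensillum archetype preset
#'
#' Editable configuration of the generative tuning of the six sensillum
#' types, expressed as a rule table. Rules are applied in order to each
#' (sensillum, odorant) cell; later rules override earlier ones, and
#' odorant-level rules override class-level rules. A class-level rule with
#' `responder_fraction` < 1 assigns evoked rates linearly spaced from
#' `rate_hi` down to `rate_lo` to the first `ceiling(fraction * n)` class
#' members in panel order, and `rate_rest` to the remainder.
#'
#' The preset encodes the qualitative structure of bed-bug antennal tuning:
#' aldehyde-dominated D sensilla (with nonanal the strongest stimulus of
#' all, ~248/213/223 spikes/s on D-alpha/beta/gamma), an amine-dominated
#' grooved-peg C sensillum that also responds to two heterocyclics, a
#' nearly silent E1, an E2 tuned to long-chain (>C10) compounds, and no
#' excitatory response to any carboxylic acid. Kernels follow the observed
#' temporal dynamics: short-chain aldehydes (propanal, butanal) and decanal
#' phasic; pentanal-nonanal tonic; sulcatone tonic while the aliphatic
#' ketones and the aromatics are phasic.
#'
#' @param reference_dose log10 v/v dilution at which the rule rates are
#'   calibrated (default -2, i.e. 1:100).
#' @return A list of class `archetype_preset`: `rules` (data.frame),
#'   `baselines` (named numeric, spikes/s), `reference_dose`, and default
#'   Hill parameters `ec50_dose` and `hill`.
#' @export
default_archetypes <- function(reference_dose = -2) {
  r <- function(sensillum, match_type, match, rate_hi, rate_lo = rate_hi,
                responder_fraction = 1, rate_rest = 0, kernel = "phasic",
                tau = 0.2)
    data.frame(sensillum, match_type, match, rate_hi, rate_lo,
               responder_fraction, rate_rest, kernel, tau,
               stringsAsFactors = FALSE)
  rules <- rbind(
    # class-level structure (fractions ~ Fig-2B-style response biases)
    r("Da", "class", "aldehyde", 120, 55, 0.55, 8, "tonic", NA),
    r("Da", "class", "alcohol", 120, 60, 0.15, 5, "tonic", NA),
    r("Da", "class", "heterocyclic", 70, 55, 0.15, 4),
    r("Db", "class", "aldehyde", 160, 55, 0.82, 10, "tonic", NA),
    r("Db", "class", "alcohol", 100, 52, 0.38, 8, "tonic", NA),
    r("Db", "class", "aromatic_aliphatic", 90, 52, 0.30, 6),
    r("Dg", "class", "aldehyde", 150, 55, 0.64, 8, "tonic", NA),
    r("Dg", "class", "aromatic_aliphatic", 110, 52, 0.26, 5),
    r("Dg", "class", "heterocyclic", 75, 55, 0.15, 4),
    # amine / heterocyclic tuning of the grooved-peg C sensillum
    r("C", "odorant", "ammonia", 200, kernel = "tonic", tau = NA),
    r("C", "odorant", "propylamine", 195, kernel = "tonic", tau = NA),
    r("C", "odorant", "butylamine", 144, kernel = "tonic", tau = NA),
    r("C", "odorant", "1-methylpiperazine", 176),
    r("C", "odorant", "thiazolidine", 130),
    # E1: nearly silent
    r("E1", "odorant", "octanal", 30),
    r("E1", "odorant", "methyl tridecanoate", 23),
    # E2: long-chain compounds
    r("E2", "odorant", "N-pentadecanoic acid", 49),
    r("E2", "odorant", "1-tetradecene", 60),
    r("E2", "odorant", "lauroyl chloride", 58.8),
    r("E2", "odorant", "1-chlorododecane", 57),
    r("E2", "odorant", "hexadecane", 35),
    r("E2", "odorant", "1-hexadecene", 42),
    r("E2", "odorant", "methyl tridecanoate", 31),
    r("E2", "odorant", "1-chlorotetradecane", 39),
    r("E2", "odorant", "1-chlorohexadecane", 20),
    # named strong D-sensillum responders
    r("Da", "odorant", "nonanal", 248, kernel = "tonic", tau = NA),
    r("Db", "odorant", "nonanal", 213, kernel = "tonic", tau = NA),
    r("Dg", "odorant", "nonanal", 223, kernel = "tonic", tau = NA),
    r("Da", "odorant", "octanal", 135, kernel = "tonic", tau = NA),
    r("Db", "odorant", "octanal", 200, kernel = "tonic", tau = NA),
    r("Dg", "odorant", "octanal", 162, kernel = "tonic", tau = NA),
    r("Da", "odorant", "decanal", 74),
    r("Db", "odorant", "decanal", 85),
    r("Dg", "odorant", "decanal", 108),
    r("Da", "odorant", "propanal", 55),
    r("Da", "odorant", "butanal", 58),
    r("Dg", "odorant", "propanal", 55),
    r("Dg", "odorant", "butanal", 58),
    r("Da", "odorant", "1-chlorohexane", 136),
    r("Db", "odorant", "1-chloroheptane", 146),
    r("Db", "odorant", "1-chlorohexane", 131),
    r("Db", "odorant", "2-pentanone", 102),
    r("Db", "odorant", "2-hexanone", 138),
    r("Db", "odorant", "2-decanone", 100),
    r("Db", "odorant", "3-pentanone", 122),
    r("Dg", "odorant", "2-hexanone", 111),
    r("Dg", "odorant", "sulcatone", 226, kernel = "tonic", tau = NA),
    # the stereoisomer pair: near-identical tuning on Da
    r("Da", "odorant", "cis-2-hexen-1-ol", 120, kernel = "tonic", tau = NA),
    r("Da", "odorant", "trans-2-hexen-1-ol", 115, kernel = "tonic",
      tau = NA)
  )
  structure(list(
    rules = rules,
    baselines = c(Da = 10, Db = 10, Dg = 10, C = 15, E1 = 5, E2 = 5),
    reference_dose = reference_dose,
    ec50_dose = -3.5,
    hill = 1),
    class = "archetype_preset")
}

# Expand an archetype preset over a panel into one response_profile per
# (sensillum, odorant) cell. Rates in the rule table are rates *at the
# reference dose*; the profile's max_evoked_rate is back-computed from the
# Hill curve so the realized rate at the reference dose equals the rule
# rate.
expand_archetypes <- function(preset, panel) {
  stopifnot(inherits(preset, "archetype_preset"))
  sens <- names(sensillum_types())
  cells <- expand.grid(odorant = panel$odorant, sensillum = sens,
                       stringsAsFactors = FALSE)
  cells$class <- panel$class[match(cells$odorant, panel$odorant)]
  cells$rate <- 0
  cells$kernel <- "phasic"
  cells$tau <- 0.2
  for (i in seq_len(nrow(preset$rules))) {
    rule <- preset$rules[i, ]
    if (rule$match_type == "class") {
      if (!rule$match %in% odorant_classes())
        stop_schema("archetype rule refers to unknown class: ", rule$match)
      # rules for classes/odorants absent from a reduced panel are inert
      members <- panel$odorant[panel$class == rule$match]
      if (!length(members)) next
      n_resp <- round(rule$responder_fraction * length(members))
      rates <- rep(rule$rate_rest, length(members))
      if (n_resp > 0)
        rates[seq_len(n_resp)] <-
          seq(rule$rate_hi, rule$rate_lo, length.out = n_resp)
      idx <- match(
        paste(rule$sensillum, members),
        paste(cells$sensillum, cells$odorant))
      cells$rate[idx] <- rates
      cells$kernel[idx] <- rule$kernel
      cells$tau[idx] <- rule$tau
    } else {
      idx <- which(cells$sensillum == rule$sensillum &
                     cells$odorant == rule$match)
      if (!length(idx)) next
      cells$rate[idx] <- rule$rate_hi
      cells$kernel[idx] <- rule$kernel
      cells$tau[idx] <- rule$tau
    }
  }
  # back out the Hill asymptote so rate-at-reference-dose == rule rate
  hill_factor <- 1 + 10^((preset$ec50_dose - preset$reference_dose) *
                           preset$hill)
  profiles <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    profiles[[i]] <- response_profile(
      sensillum_type = cells$sensillum[i],
      odorant_id = cells$odorant[i],
      baseline_rate = unname(preset$baselines[cells$sensillum[i]]),
      max_evoked_rate = cells$rate[i] * hill_factor,
      kernel = cells$kernel[i],
      phasic_decay_constant =
        if (cells$kernel[i] == "phasic") cells$tau[i] else NULL,
      ec50_dose = preset$ec50_dose,
      hill_coefficient = preset$hill)
  }
  cells$profile <- profiles
  cells
}
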