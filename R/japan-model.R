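# The Japan new-drug pricing decision evaluation model: five premium
# subsystems (value, marketability I/II, pediatrics, SAKIGAKE) scored from
# dimensionless criteria, feeding a weighted flow into one accumulating stock.
#
# Each scored criterion appears twice: as a "<name> score" constant holding
# the assigned score, and as a same-named auxiliary carrying it into the
# algebra — mirroring the constant-into-auxiliary structure of the source
# stock-and-flow diagram. The three special-designation rows (rare disease,
# small market, children) share one base constant.

japan_scores <- c(
  "serious diseases without standard treatment"            = 1,
  "additional clinical significance of nhs accreditation"  = 1,
  "safety better than comparator"                          = 1,
  "evidence from rct"                                      = 2,
  "evidence from other"                                    = 1,
  "favouring patient groups with poor outcomes"            = 1,
  "becoming a standard treatment option"                   = 1,
  "faster onset/longing effects"                           = 1,
  "combination to enhance effectiveness"                   = 1,
  "reducing invasiveness of drug delivery"                 = 1,
  "easy administration"                                    = 1,
  "stable blood level"                                     = 1,
  "new mechanism"                                          = 2,
  "major disease"                                          = 2,
  "significant improvement in efficacy"                    = 2,
  "japan premiere/global synchronisation"                  = 2
)

japan_flow_weights <- c(
  "value premium"            = 1.800,
  "marketability premium i"  = 1.150,
  "marketability premium ii" = 1.050,
  "pediatrics premium"       = 1.125,
  "sakigake premium"         = 1.150
)

# delay time constants, in years
JAPAN_EFFICACY_DELAY <- 0.5
JAPAN_DESIGNATION_DELAY <- 5

japan_expression_vars <- function(base_refs) {
  # base_refs: named character, one base-constant name per special row
  list(
    sd_aux("new action part", sd_lit(2), sd_ref("new mechanism")),
    sd_aux("new target", sd_lit(1), sd_ref("new mechanism")),
    sd_aux("validity better than comparator",
           sd_lit(2),
           sd_delay1("significant improvement in efficacy", JAPAN_EFFICACY_DELAY),
           sd_ref("combination to enhance effectiveness")),
    sd_aux("no standard in disease areas",
           sd_lit(1), sd_ref("serious diseases without standard treatment")),
    sd_aux("rare disease drug",
           sd_ref(base_refs[["rare disease drug"]]),
           sd_delay1("sakigake premium", JAPAN_DESIGNATION_DELAY)),
    sd_aux("small market size",
           sd_ref(base_refs[["small market size"]]),
           sd_delay1("sakigake premium", JAPAN_DESIGNATION_DELAY)),
    sd_aux("children's drug",
           sd_ref(base_refs[["children's drug"]]),
           sd_delay1("sakigake premium", JAPAN_DESIGNATION_DELAY)),
    sd_aux("new clinically useful mechanism",
           sd_ref("additional clinical significance of nhs accreditation"),
           sd_ref("new action part"),
           sd_ref("new target"),
           sd_ref("serious diseases without standard treatment")),
    sd_aux("more effective/safe than comparable drugs",
           sd_ref("additional clinical significance of nhs accreditation"),
           sd_ref("safety better than comparator"),
           sd_ref("validity better than comparator"),
           sd_ref("evidence from rct"),
           sd_ref("evidence from other")),
    sd_aux("may improve disease or injury",
           sd_ref("additional clinical significance of nhs accreditation"),
           sd_ref("becoming a standard treatment option"),
           sd_ref("favouring patient groups with poor outcomes"),
           sd_ref("no standard in disease areas"),
           sd_ref("combination to enhance effectiveness"),
           sd_ref("faster onset/longing effects")),
    sd_aux("formulation improvements to enhance utility",
           sd_ref("reducing invasiveness of drug delivery"),
           sd_ref("easy administration"),
           sd_ref("stable blood level"),
           sd_ref("additional clinical significance of nhs accreditation")),
    sd_aux("value premium",
           sd_ref("formulation improvements to enhance utility"),
           sd_ref("may improve disease or injury"),
           sd_ref("new clinically useful mechanism"),
           sd_ref("more effective/safe than comparable drugs")),
    sd_aux("marketability premium i", sd_ref("rare disease drug")),
    sd_aux("marketability premium ii", sd_ref("small market size")),
    sd_aux("pediatrics premium", sd_ref("children's drug")),
    sd_aux("sakigake premium",
           sd_ref("new mechanism"),
           sd_ref("significant improvement in efficacy"),
           sd_ref("japan premiere/global synchronisation"),
           sd_ref("major disease")),
    sd_aux("new drug pricing decision variation",
           sd_ref("value premium", japan_flow_weights[["value premium"]]),
           sd_ref("marketability premium i", japan_flow_weights[["marketability premium i"]]),
           sd_ref("marketability premium ii", japan_flow_weights[["marketability premium ii"]]),
           sd_ref("pediatrics premium", japan_flow_weights[["pediatrics premium"]]),
           sd_ref("sakigake premium", japan_flow_weights[["sakigake premium"]])),
    sd_stock("new drug pricing decision evaluation",
             inflow = "new drug pricing decision variation", initial = 0)
  )
}

#' Build the Japan new-drug pricing decision evaluation model
#'
#' Constructs the bundled model: 17 constants (16 criterion scores plus one
#' shared special-designation base of 5), 33 auxiliaries and a single stock
#' ("new drug pricing decision evaluation") integrating the weighted flow
#' `1.8 * value premium + 1.15 * marketability premium I +
#' 1.05 * marketability premium II + 1.125 * pediatrics premium +
#' 1.15 * SAKIGAKE premium`, with initial value 0. Two first-order delays
#' carry time lags: the efficacy signal into "validity better than
#' comparator" (0.5 years) and the SAKIGAKE premium into each of the three
#' special-designation drug scores (5 years).
#'
#' @return A validated `sd_model`.
#' @seealso [japan_catalog()], [run_baseline()]
#' @export
japan_pricing_model <- function() {
  consts <- c(
    lapply(names(japan_scores), function(nm) {
      sd_constant(paste(nm, "score"), japan_scores[[nm]])
    }),
    list(sd_constant("special designation base", 5))
  )
  score_aux <- lapply(names(japan_scores), function(nm) {
    sd_aux(nm, sd_ref(paste(nm, "score")))
  })
  base_refs <- c("rare disease drug" = "special designation base",
                 "small market size" = "special designation base",
                 "children's drug" = "special designation base")
  sd_model(c(consts, score_aux, japan_expression_vars(base_refs)),
           name = "japan-new-drug-pricing",
           description = paste(
             "New drug pricing decision evaluation for Japan's premium system:",
             "value, marketability I/II, pediatrics and SAKIGAKE premium",
             "subsystems feeding a weighted accumulating evaluation stock."))
}

#' Variant with per-row special-designation base constants
#'
#' The bundled model shares a single base constant (5) across the rare
#' disease, small market and children's drug rows, so a one-at-a-time
#' perturbation of that constant moves all three rows together. This variant
#' splits the base into three independent constants ("rare disease base",
#' "small market base", "children base", each 5) so the three
#' special-designation premiums can be perturbed individually; its census is
#' 19 constants, 33 auxiliaries, 1 stock. Baseline behaviour is identical to
#' [japan_pricing_model()].
#'
#' @return A validated `sd_model`.
#' @export
japan_special_premium_model <- function() {
  consts <- c(
    lapply(names(japan_scores), function(nm) {
      sd_constant(paste(nm, "score"), japan_scores[[nm]])
    }),
    list(sd_constant("rare disease base", 5),
         sd_constant("small market base", 5),
         sd_constant("children base", 5))
  )
  score_aux <- lapply(names(japan_scores), function(nm) {
    sd_aux(nm, sd_ref(paste(nm, "score")))
  })
  base_refs <- c("rare disease drug" = "rare disease base",
                 "small market size" = "small market base",
                 "children's drug" = "children base")
  sd_model(c(consts, score_aux, japan_expression_vars(base_refs)),
           name = "japan-new-drug-pricing-split-base",
           description = "Special-designation bases split into per-row constants.")
}

#' Catalog of the Japan pricing model
#'
#' Names and roles of the bundled model's variables: the criterion-score
#' constants with their printed spellings and base values, the five premium
#' subsystem auxiliaries in reporting order, the flow and stock names, and
#' the flow weights.
#'
#' @return A list with elements `constants` (data frame: `printed`, `constant`,
#'   `auxiliary`, `value`), `subsystems` (five premium auxiliary names),
#'   `flow_weights` (named numeric, aligned to `subsystems`), `flow`
#'   and `stock` (names), `delay_times` (named numeric, years).
#' @export
japan_catalog <- function() {
  printed <- c(
    "Serious diseases without standard treatment",
    "Additional clinical significance of NHS accreditation",
    "Safety better than comparator",
    "Evidence from RCT",
    "Evidence from other",
    "Favouring patient groups with poor outcomes",
    "Becoming a standard treatment option",
    "Faster onset/longing effects",
    "Combination to enhance effectiveness",
    "Reducing invasiveness of drug delivery",
    "Easy administration",
    "Stable blood level",
    "New mechanism",
    "Major disease",
    "Significant improvement in efficacy",
    "Japan premiere/global synchronisation")
  constants <- data.frame(
    printed = printed,
    constant = paste(names(japan_scores), "score"),
    auxiliary = names(japan_scores),
    value = unname(japan_scores),
    stringsAsFactors = FALSE)
  list(constants = constants,
       subsystems = names(japan_flow_weights),
       flow_weights = japan_flow_weights,
       flow = "new drug pricing decision variation",
       stock = "new drug pricing decision evaluation",
       delay_times = c("efficacy signal" = JAPAN_EFFICACY_DELAY,
                       "special designation" = JAPAN_DESIGNATION_DELAY))
}

#' Map a criterion name to its score constant
#'
#' Accepts a constant name, an auxiliary criterion name, or the printed
#' spelling from the catalog, and returns the model constant holding its
#' score.
#'
#' @param name Criterion identifier.
#' @return Constant variable name.
#' @export
japan_constant_for <- function(name) {
  cat_ <- japan_catalog()$constants
  key <- tolower(name)
  if (key %in% cat_$constant) return(key)
  i <- match(key, cat_$auxiliary)
  if (is.na(i)) i <- match(key, tolower(cat_$printed))
  if (is.na(i)) {
    if (key %in% c("special designation base", "rare disease base",
                   "small market base", "children base")) return(key)
    stop(sprintf("unknown criterion '%s'", name))
  }
  cat_$constant[i]
}

#' Premium subsystem values at a time point
#'
#' @param traj An `sd_trajectory` from the Japan model.
#' @param t Time on the save grid.
#' @return Named numeric vector of the five premium values (value,
#'   marketability I, marketability II, pediatrics, SAKIGAKE), in catalog
#'   order.
#' @export
premium_components <- function(traj, t) {
  stopifnot(inherits(traj, "sd_trajectory"))
  i <- match_time(traj, t)
  subs <- japan_catalog()$subsystems
  missing <- setdiff(subs, colnames(traj$values))
  if (length(missing)) {
    stop(sprintf("trajectory lacks premium variables: %s",
                 paste(missing, collapse = ", ")))
  }
  stats::setNames(traj$values[i, subs], subs)
}
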