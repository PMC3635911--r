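#' Catalogue of randomised comparative designs for small populations
#'
#' The registry holds one profile per design: twelve randomised comparative
#' designs usable when recruitment is limited (adaptive randomisation
#' variants are grouped as one entry). Each profile records the
#' selection-relevant attributes that drive the decision algorithm
#' (\code{\link{select_designs}}) together with advisory annotations
#' (advantages, limitations) that never affect selection.
#'
#' Attributes:
#' \describe{
#'   \item{comparison_basis}{\code{"inter_patient"} or \code{"intra_patient"};
#'     intra-patient designs (cross-over, Latin square, N-of-1) use each
#'     patient as their own control.}
#'   \item{requires_reversible_outcome}{designs that re-expose a patient, or
#'     withdraw an effective treatment, need an outcome that can return to
#'     its pre-treatment state.}
#'   \item{requires_stable_chronic_disease}{advisory: within-patient and
#'     withdrawal-type designs assume a stable chronic condition.}
#'   \item{requires_binary_outcome}{advisory: urn-adaptive, early-escape and
#'     three-stage designs need a success/failure endpoint.}
#'   \item{minimizes_time_on_placebo}{the design reduces cumulative placebo
#'     (or treatment-failure) exposure relative to a parallel trial.}
#'   \item{placebo_minimization_requires_fast_response}{the placebo-sparing
#'     mechanism only works when responses are observable within a few
#'     weeks, because it reacts to observed outcomes (withdrawal,
#'     early escape, three-stage, adaptive randomisation).}
#'   \item{all_patients_active_at_end}{every enrolled patient is on active
#'     treatment by the end of the trial (delayed start, randomised
#'     placebo-phase, stepped wedge).}
#' }
#'
#' @return A data frame with 12 rows, one per design, with list columns
#'   \code{advantages} and \code{limitations}.
#' @examples
#' reg <- design_registry()
#' nrow(reg)                                  # 12
#' sum(reg$minimizes_time_on_placebo)         # 7
#' reg$name[reg$all_patients_active_at_end]   # the three all-active designs
#' @seealso \code{\link{design_profile}}, \code{\link{select_designs}}
#' @export
design_registry <- function() {
  reg <- .registry_table()
  .check_registry(reg)
  reg
}

#' Valid design identifiers
#'
#' @return Character vector of the 12 design identifiers, in registry order.
#' @export
design_names <- function() {
  c("parallel", "factorial", "crossover", "latin_square", "n_of_1",
    "delayed_start", "placebo_phase", "stepped_wedge",
    "randomized_withdrawal", "early_escape", "three_stage",
    "adaptive_randomization")
}

.registry_table <- function() {
  nm <- design_names()
  intra  <- c("crossover", "latin_square", "n_of_1")
  revr   <- c("crossover", "latin_square", "n_of_1", "randomized_withdrawal",
              "three_stage", "early_escape", "delayed_start")
  chron  <- c("crossover", "latin_square", "n_of_1", "randomized_withdrawal",
              "three_stage")
  binr   <- c("adaptive_randomization", "early_escape", "three_stage")
  minpl  <- c("delayed_start", "placebo_phase", "stepped_wedge",
              "randomized_withdrawal", "early_escape", "three_stage",
              "adaptive_randomization")
  fastpl <- c("randomized_withdrawal", "early_escape", "three_stage",
              "adaptive_randomization")
  allact <- c("delayed_start", "placebo_phase", "stepped_wedge")
  # designs whose mechanics react patient-by-patient to observed outcomes,
  # so they need responses observable within a few weeks even when
  # placebo-sparing is not requested
  needfast <- c("adaptive_randomization", "early_escape")

  adv <- list(
    parallel = c("Simple to understand and implement",
                 "Groups can have different numbers of patients",
                 "Analysis and interpretation of results is simple"),
    factorial = c("Answers two or more questions with one trial",
                  "Requires fewer patients for two questions",
                  "Time-saving for the trial sponsor"),
    crossover = c("Smaller sample size than parallel groups",
                  "Results depend only on within-patient variability"),
    latin_square = c("Compares more than two treatments",
                     "Balanced: each treatment once per sequence and period",
                     "Smaller sample size than parallel groups"),
    n_of_1 = c("Estimates individual effectiveness (personalised medicine)",
               "Better adherence and understanding by the patient"),
    delayed_start = c("More patients receive active treatment",
                      "Distinguishes symptomatic from disease-modifying effects"),
    placebo_phase = c("All patients receive active treatment",
                      "Usable for disease-modifying therapies in rapidly evolving disease"),
    stepped_wedge = c("Useful when treatment is believed to do more good than harm",
                      "Suits interventions that cannot be delivered to all units at once"),
    randomized_withdrawal = c("Reduces time on placebo: only responders are randomised to placebo",
                              "Assesses whether treatment must be continued"),
    early_escape = c("Reduces time on placebo or in treatment failure",
                     "Minimises exposure to ineffective treatment"),
    three_stage = c("Three independent efficacy assessments combined by Fisher's method",
                    "Fewer patients than a parallel-group design",
                    "Reduces time on placebo or non-efficacious treatment"),
    adaptive_randomization = c("Fewer patients receive the less effective treatment",
                               "May improve recruitment through better patient satisfaction")
  )
  lim <- list(
    parallel = c("Larger sample size often required than other designs",
                 "Recruitment difficulties possible if placebo-controlled",
                 "Cannot separate inter- and intra-patient variability"),
    factorial = c("Requires no interaction between the two treatments"),
    crossover = c("Stable chronic diseases only: patient state must be comparable at the start of both periods",
                  "Requires a wash-out period between treatment periods",
                  "Follow-up at least twice as long as a parallel trial",
                  "Analysis must confirm absence of treatment-period interaction"),
    latin_square = c("Same as cross-over, though carry-over is controlled by balance"),
    n_of_1 = c("Same as cross-over; needs a stable chronic disease",
               "Conclusions apply to the single studied patient"),
    delayed_start = c("Groups not comparable at the start of the second phase",
                      "No real blinding in the second period; carry-over possible"),
    placebo_phase = c("Variable placebo-period length reduces statistical power",
                      "Limited ability to estimate the size of the treatment effect"),
    stepped_wedge = c("Risk of contamination between intervention participants",
                      "Needs blinded outcome assessment"),
    randomized_withdrawal = c("Chronic diseases only; unsuitable for spontaneous remission or slow evolution",
                              "Treatment effect overestimated: only responders are compared",
                              "Possible carry-over of adverse effects"),
    early_escape = c("Binary failure/success outcome can be hard to define",
                     "Only short-term efficacy evaluated",
                     "Loss of power if many patients escape"),
    three_stage = c("Chronic conditions only: response and withdrawal must both be assessable",
                    "Withdrawal phase must allow full wash-out",
                    "Marginal responders forgo active treatment",
                    "Less suited to controlled safety assessment"),
    adaptive_randomization = c("Unequal sample sizes reduce power",
                               "Needs a binary success/failure outcome",
                               "One arm may end up with very few patients",
                               "No clear methodology for delayed responses")
  )

  data.frame(
    name = nm,
    comparison_basis = ifelse(nm %in% intra, "intra_patient", "inter_patient"),
    requires_reversible_outcome = nm %in% revr,
    requires_stable_chronic_disease = nm %in% chron,
    requires_binary_outcome = nm %in% binr,
    requires_fast_response = nm %in% needfast,
    minimizes_time_on_placebo = nm %in% minpl,
    placebo_minimization_requires_fast_response = nm %in% fastpl,
    all_patients_active_at_end = nm %in% allact,
    advantages = I(adv[nm]),
    limitations = I(lim[nm]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

.check_registry <- function(reg) {
  fail <- function(what) {
    stop("design registry internal consistency failure: ", what, call. = FALSE)
  }
  if (nrow(reg) != 12L) fail("exactly 12 profiles must exist")
  if (anyDuplicated(reg$name)) fail("design names must be unique")
  if (sum(reg$comparison_basis == "intra_patient") != 3L)
    fail("exactly 3 designs must be intra-patient")
  if (sum(reg$minimizes_time_on_placebo) != 7L)
    fail("exactly 7 designs must minimise time on placebo")
  if (sum(reg$all_patients_active_at_end) != 3L)
    fail("exactly 3 designs must have all patients active at the end")
  if (any(reg$all_patients_active_at_end & !reg$minimizes_time_on_placebo))
    fail("all-patients-active-at-end implies minimises time on placebo")
  invisible(TRUE)
}

#' Look up one design profile
#'
#' @param name A design identifier; see \code{\link{design_names}}.
#' @return A one-row data frame (the matching registry row).
#' @examples
#' design_profile("crossover")$comparison_basis     # "intra_patient"
#' design_profile("randomized_withdrawal")$minimizes_time_on_placebo  # TRUE
#' @export
design_profile <- function(name) {
  reg <- design_registry()
  if (length(name) != 1L || !is.character(name) || !name %in% reg$name) {
    stop("unknown design ", dQuote(as.character(name)[1]),
         "; valid identifiers are: ", paste(reg$name, collapse = ", "),
         call. = FALSE)
  }
  reg[reg$name == name, , drop = FALSE]
}

#' Export the design registry as JSON
#'
#' One JSON object per design, attribute names as in
#' \code{\link{design_registry}}; used by the command-line \code{registry}
#' subcommand for documentation and audit.
#'
#' @param path Optional file path; if \code{NULL} the JSON string is returned.
#' @return The JSON string, invisibly when written to \code{path}.
#' @export
registry_json <- function(path = NULL) {
  reg <- design_registry()
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    r <- as.list(reg[i, setdiff(names(reg), c("advantages", "limitations"))])
    r$advantages <- unlist(reg$advantages[[i]], use.names = FALSE)
    r$limitations <- unlist(reg$limitations[[i]], use.names = FALSE)
    r
  })
  js <- jsonlite::toJSON(rows, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
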