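#' Describe a disease-treatment-outcome scenario for design selection
#'
#' A decision context is the set of answers to the five decision nodes used
#' by the selection algorithm: whether the outcome is reversible, whether
#' the response to treatment is observable quickly (within a few weeks) or
#' slowly, whether time on placebo must be minimised, whether every patient
#' must be on active treatment by the end of the trial, and whether an
#' intra-patient or inter-patient comparison is preferred.
#'
#' @param outcome_reversible Logical. Can the outcome return to its
#'   pre-treatment state once treatment is withdrawn?
#' @param response_speed \code{"fast"} (response observable within up to a
#'   few weeks) or \code{"slow"}.
#' @param minimize_placebo_time \code{"required"} or \code{"indifferent"}.
#' @param all_active_at_end \code{"required"} or \code{"indifferent"}.
#' @param comparison_preference \code{"intra_patient"}, \code{"inter_patient"}
#'   or \code{"indifferent"}.
#' @return An object of class \code{decision_context}.
#' @examples
#' decision_context(TRUE, "fast", minimize_placebo_time = "required")
#' @export
decision_context <- function(outcome_reversible,
                             response_speed = c("fast", "slow"),
                             minimize_placebo_time = c("indifferent", "required"),
                             all_active_at_end = c("indifferent", "required"),
                             comparison_preference = c("indifferent",
                                                       "intra_patient",
                                                       "inter_patient")) {
  stopifnot(is.logical(outcome_reversible), length(outcome_reversible) == 1L,
            !is.na(outcome_reversible))
  ctx <- structure(list(
    outcome_reversible = outcome_reversible,
    response_speed = match.arg(response_speed),
    minimize_placebo_time = match.arg(minimize_placebo_time),
    all_active_at_end = match.arg(all_active_at_end),
    comparison_preference = match.arg(comparison_preference)
  ), class = "decision_context")
  ctx
}

#' @export
print.decision_context <- function(x, ...) {
  cat("Decision context\n")
  cat("  outcome reversible:    ", x$outcome_reversible, "\n")
  cat("  response speed:        ", x$response_speed, "\n")
  cat("  minimise placebo time: ", x$minimize_placebo_time, "\n")
  cat("  all active at end:     ", x$all_active_at_end, "\n")
  cat("  comparison preference: ", x$comparison_preference, "\n")
  invisible(x)
}

# node filters, applied in the fixed node order; each returns the names the
# node removes from the currently feasible set
.node_filters <- list(
  reversibility = function(reg, ctx) {
    if (ctx$outcome_reversible) character(0)
    else reg$name[reg$requires_reversible_outcome]
  },
  response_speed = function(reg, ctx) {
    if (ctx$response_speed == "fast") character(0)
    else reg$name[reg$requires_fast_response]
  },
  placebo_minimization = function(reg, ctx) {
    if (ctx$minimize_placebo_time != "required") return(character(0))
    keep <- reg$minimizes_time_on_placebo
    if (ctx$response_speed == "slow")
      keep <- keep & !reg$placebo_minimization_requires_fast_response
    reg$name[!keep]
  },
  all_active = function(reg, ctx) {
    if (ctx$all_active_at_end != "required") character(0)
    else reg$name[!reg$all_patients_active_at_end]
  },
  comparison_basis = function(reg, ctx) {
    if (ctx$comparison_preference == "indifferent") character(0)
    else reg$name[reg$comparison_basis != ctx$comparison_preference]
  }
)

#' Select feasible trial designs for a scenario
#'
#' Applies the five decision nodes in fixed order (outcome reversibility,
#' response speed, placebo-time minimisation, all-patients-active-at-end,
#' comparison basis) to the design registry. Each excluded design is tagged
#' with the first node that removed it; since the nodes act by set
#' intersection, the feasible set itself does not depend on node order.
#'
#' @param ctx A \code{\link{decision_context}}.
#' @return An object of class \code{design_selection} with components
#'   \code{feasible} (design identifiers, registry order), \code{excluded}
#'   (data frame with columns \code{design}, \code{node}), \code{caveats}
#'   (character) and \code{context}.
#' @examples
#' # a reversible outcome with a rapid response leaves all 12 designs open
#' sel <- select_designs(decision_context(TRUE, "fast"))
#' length(sel$feasible)
#' # requiring minimal time on placebo narrows the set to 7
#' sel <- select_designs(decision_context(TRUE, "fast",
#'                                        minimize_placebo_time = "required"))
#' sel$feasible
#' @export
select_designs <- function(ctx) {
  if (!inherits(ctx, "decision_context"))
    stop("ctx must be a decision_context", call. = FALSE)
  reg <- design_registry()
  feasible <- reg$name
  excluded <- data.frame(design = character(0), node = character(0),
                         stringsAsFactors = FALSE)
  for (node in names(.node_filters)) {
    out <- intersect(feasible, .node_filters[[node]](reg, ctx))
    if (length(out)) {
      excluded <- rbind(excluded,
                        data.frame(design = out, node = node,
                                   stringsAsFactors = FALSE))
      feasible <- setdiff(feasible, out)
    }
  }
  caveats <- paste("Feasibility reflects the decision nodes only;",
                   "contextual constraints (e.g. both arms being active",
                   "treatments) can rule out designs the algorithm keeps.")
  if (!length(feasible))
    caveats <- c(caveats, "no catalogued design satisfies constraints")
  structure(list(feasible = feasible, excluded = excluded,
                 caveats = caveats, context = ctx),
            class = "design_selection")
}

#' @export
print.design_selection <- function(x, ...) {
  cat("Design selection:", length(x$feasible), "of 12 designs feasible\n")
  if (length(x$feasible))
    cat("  feasible:", paste(x$feasible, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat("  excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat("    ", x$excluded$design[i], " (node: ", x$excluded$node[i], ")\n",
          sep = "")
  }
  invisible(x)
}

#' Annotated report for a design selection
#'
#' Attaches the registry's advantages and limitations to every feasible
#' design and the excluding node to every excluded design.
#'
#' @param result A \code{design_selection} from \code{\link{select_designs}}.
#' @return A list of class \code{selection_report} with components
#'   \code{feasible} (named list: advantages, limitations per design),
#'   \code{excluded} (data frame design/node) and \code{caveats}.
#' @export
explain_selection <- function(result) {
  if (!inherits(result, "design_selection"))
    stop("result must come from select_designs()", call. = FALSE)
  reg <- design_registry()
  feas <- lapply(result$feasible, function(nm) {
    i <- match(nm, reg$name)
    list(design = nm,
         comparison_basis = reg$comparison_basis[i],
         advantages = reg$advantages[[i]],
         limitations = reg$limitations[[i]])
  })
  names(feas) <- result$feasible
  structure(list(feasible = feas, excluded = result$excluded,
                 caveats = result$caveats),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection report:", length(x$feasible), "feasible design(s)\n")
  for (f in x$feasible) {
    cat("\n*", f$design, "(", f$comparison_basis, ")\n")
    cat("  advantages: ", paste(f$advantages, collapse = "; "), "\n")
    cat("  limitations:", paste(f$limitations, collapse = "; "), "\n")
  }
  if (nrow(x$excluded)) {
    cat("\nExcluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat("  ", x$excluded$design[i], "- node:", x$excluded$node[i], "\n")
  }
  for (cv in x$caveats) cat("\nNote:", cv, "\n")
  invisible(x)
}
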