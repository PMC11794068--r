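# Declarative model specification: constants, auxiliaries (linear expressions
# over literals, references and first-order delays) and Euler-integrated stocks.

#' Literal expression term
#'
#' Builds one additive element of an auxiliary expression. An auxiliary's value
#' is the sum of its terms; each term is `coefficient * x` where `x` is a
#' literal number, the current value of another variable, or the output of a
#' first-order information delay applied to another variable.
#'
#' @param value Literal numeric value.
#' @param coefficient Multiplier applied to the term (default 1).
#' @return An object of class `sd_term`.
#' @seealso [sd_ref()], [sd_delay1()], [sd_aux()]
#' @export
sd_lit <- function(value, coefficient = 1) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(coefficient), length(coefficient) == 1L, is.finite(coefficient))
  structure(list(coefficient = as.numeric(coefficient), kind = "literal",
                 literal = as.numeric(value)),
            class = "sd_term")
}

#' Reference expression term
#'
#' @param source Name of the referenced variable.
#' @param coefficient Multiplier applied to the referenced value (default 1).
#' @return An object of class `sd_term`.
#' @export
sd_ref <- function(source, coefficient = 1) {
  stopifnot(is.character(source), length(source) == 1L, nzchar(source),
            is.numeric(coefficient), length(coefficient) == 1L, is.finite(coefficient))
  structure(list(coefficient = as.numeric(coefficient), kind = "ref",
                 source = source),
            class = "sd_term")
}

#' First-order information delay term
#'
#' The delay output `y` relaxes towards its input `u` (the value of `source`)
#' with time constant `delay_time`: one Euler step updates
#' `y <- y + (dt / delay_time) * (u - y)`. The initial output is set by
#' `init_policy`:
#' \describe{
#'   \item{default}{zero when `delay_time >= dt`, otherwise equilibrium.
#'     Short delays relax within a single step, so starting them at their
#'     input avoids a spurious one-step transient (and, at
#'     `delay_time < dt/2`, an oscillatory Euler artefact).}
#'   \item{zero}{start at 0 (the policy signal has no history).}
#'   \item{equilibrium}{start at the input's initial value (steady state).}
#'   \item{explicit}{start at `init_value`.}
#' }
#'
#' @param source Name of the delayed input variable.
#' @param delay_time Delay time constant, in years; strictly positive.
#' @param coefficient Multiplier applied to the delay output (default 1).
#' @param init_policy One of `"default"`, `"zero"`, `"equilibrium"`, `"explicit"`.
#' @param init_value Initial output when `init_policy = "explicit"`.
#' @return An object of class `sd_term`.
#' @export
sd_delay1 <- function(source, delay_time, coefficient = 1,
                      init_policy = c("default", "zero", "equilibrium", "explicit"),
                      init_value = NULL) {
  init_policy <- match.arg(init_policy)
  stopifnot(is.character(source), length(source) == 1L, nzchar(source),
            is.numeric(delay_time), length(delay_time) == 1L,
            is.numeric(coefficient), length(coefficient) == 1L, is.finite(coefficient))
  if (init_policy == "explicit") {
    stopifnot(is.numeric(init_value), length(init_value) == 1L, is.finite(init_value))
    init_value <- as.numeric(init_value)
  } else if (!is.null(init_value)) {
    stop("init_value is only allowed with init_policy = \"explicit\"")
  }
  structure(list(coefficient = as.numeric(coefficient), kind = "delay1",
                 source = source,
                 delay = list(delay_time = as.numeric(delay_time),
                              init_policy = init_policy,
                              init_value = init_value)),
            class = "sd_term")
}

#' Declare a constant variable
#'
#' @param name Variable name (unique within a model).
#' @param value Constant (dimensionless score) value.
#' @return An object of class `sd_variable`.
#' @export
sd_constant <- function(name, value) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(name = name, kind = "constant", value = as.numeric(value)),
            class = "sd_variable")
}

#' Declare an auxiliary variable
#'
#' An auxiliary is recomputed every step as the sum of its terms.
#'
#' @param name Variable name.
#' @param ... `sd_term` objects ([sd_lit()], [sd_ref()], [sd_delay1()]).
#' @return An object of class `sd_variable`.
#' @export
sd_aux <- function(name, ...) {
  terms <- list(...)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!all(vapply(terms, inherits, logical(1), "sd_term"))) {
    stop("all auxiliary terms must be sd_term objects")
  }
  structure(list(name = name, kind = "auxiliary", terms = terms),
            class = "sd_variable")
}

#' Declare a stock variable
#'
#' A stock accumulates its inflow by explicit Euler steps:
#' `stock <- stock + dt * inflow`, starting from `initial`.
#'
#' @param name Variable name.
#' @param inflow Name of the variable supplying the flow rate.
#' @param initial Initial stock value (default 0).
#' @return An object of class `sd_variable`.
#' @export
sd_stock <- function(name, inflow, initial = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(inflow), length(inflow) == 1L, nzchar(inflow),
            is.numeric(initial), length(initial) == 1L, is.finite(initial))
  structure(list(name = name, kind = "stock", inflow = inflow,
                 initial = as.numeric(initial)),
            class = "sd_variable")
}

#' Assemble a system-dynamics model
#'
#' @param ... `sd_variable` objects, in declaration order (used for
#'   deterministic tie-breaking), or a single list of them.
#' @param name,description Free-form metadata strings.
#' @return An object of class `sd_model`.
#' @examples
#' m <- sd_model(
#'   sd_constant("demand", 4),
#'   sd_aux("rate", sd_lit(1), sd_ref("demand", 0.5)),
#'   sd_stock("level", inflow = "rate"),
#'   name = "toy"
#' )
#' sd_validate(m)
#' @export
sd_model <- function(..., name = "", description = "") {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) && !inherits(vars[[1]], "sd_variable")) {
    vars <- vars[[1]]
  }
  if (!all(vapply(vars, inherits, logical(1), "sd_variable"))) {
    stop("all model variables must be sd_variable objects")
  }
  nm <- vapply(vars, `[[`, character(1), "name")
  names(vars) <- nm
  structure(list(variables = vars,
                 metadata = list(name = name, description = description)),
            class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  cts <- sd_census(x)
  cat(sprintf("<sd_model> %s: %d constants, %d auxiliaries, %d stocks\n",
              if (nzchar(x$metadata$name)) x$metadata$name else "(unnamed)",
              cts[["constant"]], cts[["auxiliary"]], cts[["stock"]]))
  invisible(x)
}

variable_names <- function(spec) {
  vapply(spec$variables, `[[`, character(1), "name")
}

variable_kinds <- function(spec) {
  vapply(spec$variables, `[[`, character(1), "kind")
}

#' Count model variables by kind
#'
#' @param spec An `sd_model`.
#' @return Named integer vector with elements `constant`, `auxiliary`, `stock`.
#' @export
sd_census <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  kinds <- variable_kinds(spec)
  c(constant = sum(kinds == "constant"),
    auxiliary = sum(kinds == "auxiliary"),
    stock = sum(kinds == "stock"))
}

# ref-only aux -> aux adjacency: edges source -> dependent auxiliary
aux_ref_edges <- function(spec) {
  kinds <- variable_kinds(spec)
  aux_names <- names(spec$variables)[kinds == "auxiliary"]
  edges <- list()
  for (v in spec$variables) {
    if (v$kind != "auxiliary") next
    for (tm in v$terms) {
      if (tm$kind == "ref" && tm$source %in% aux_names) {
        edges[[length(edges) + 1L]] <- c(tm$source, v$name)
      }
    }
  }
  edges
}

# Kahn's algorithm with stable (declaration-order) tie-breaking.
# Returns list(order = character vector or NULL, cycle = names in a cycle).
topo_sort_stable <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in edges) {
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    indeg[[e[2]]] <- indeg[[e[2]]] + 1L
  }
  order <- character(0)
  remaining <- nodes
  while (length(remaining) > 0L) {
    ready <- remaining[indeg[remaining] == 0L]
    if (length(ready) == 0L) {
      return(list(order = NULL, cycle = remaining))
    }
    nxt <- ready[1L]  # declaration order preserved in `remaining`
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
    for (child in adj[[nxt]]) indeg[[child]] <- indeg[[child]] - 1L
  }
  list(order = order, cycle = character(0))
}

#' Validate a model specification
#'
#' Checks the structural preconditions of [sd_simulate()]: unique names,
#' resolvable references and delay sources, an acyclic reference graph among
#' auxiliaries (delay and stock edges carry state and may close loops),
#' strictly positive delay times, and stocks whose inflow names a declared
#' variable. Issues are returned, not raised, so a driver can report all of
#' them at once.
#'
#' @param spec An `sd_model`.
#' @return Character vector of human-readable issues; empty when the model is
#'   valid.
#' @export
sd_validate <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  issues <- character(0)
  nm <- variable_names(spec)
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) issues <- c(issues, sprintf("duplicate variable name: '%s'", d))

  declared <- unique(nm)
  for (v in spec$variables) {
    if (v$kind == "auxiliary") {
      for (tm in v$terms) {
        if (tm$kind %in% c("ref", "delay1") && !(tm$source %in% declared)) {
          issues <- c(issues, sprintf(
            "unresolved reference: '%s' refers to undeclared variable '%s'",
            v$name, tm$source))
        }
        if (tm$kind == "delay1" && tm$delay$delay_time <= 0) {
          issues <- c(issues, sprintf(
            "non-positive delay time (%g) in '%s'", tm$delay$delay_time, v$name))
        }
      }
    } else if (v$kind == "stock") {
      if (is.null(v$inflow) || !nzchar(v$inflow)) {
        issues <- c(issues, sprintf("stock '%s' has no inflow", v$name))
      } else if (!(v$inflow %in% declared)) {
        issues <- c(issues, sprintf(
          "stock '%s' has unresolved inflow '%s'", v$name, v$inflow))
      }
    }
  }

  if (length(dup) == 0L) {
    kinds <- variable_kinds(spec)
    aux_names <- nm[kinds == "auxiliary"]
    ts <- topo_sort_stable(aux_names, aux_ref_edges(spec))
    if (is.null(ts$order)) {
      issues <- c(issues, sprintf(
        "algebraic cycle among auxiliaries: {%s}",
        paste(sort(ts$cycle), collapse = ", ")))
    }
  }
  issues
}

#' Evaluation order of auxiliaries
#'
#' Topological order of the auxiliaries under reference edges. Delay sources
#' and stocks are state carried between steps and impose no ordering
#' constraint. Ties are broken by declaration order, so the result (and any
#' simulation built on it) is reproducible.
#'
#' @param spec A validated `sd_model`.
#' @return Character vector of auxiliary names in evaluation order.
#' @export
sd_dependency_order <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  kinds <- variable_kinds(spec)
  aux_names <- names(spec$variables)[kinds == "auxiliary"]
  ts <- topo_sort_stable(aux_names, aux_ref_edges(spec))
  if (is.null(ts$order)) {
    stop(sprintf("algebraic cycle among auxiliaries: {%s}",
                 paste(sort(ts$cycle), collapse = ", ")))
  }
  ts$order
}

#' Scale all constant inputs of a model
#'
#' Multiplies every constant value, literal term, stock initial and explicit
#' delay initial by `lambda`. Because every expression is linear, scaling the
#' inputs this way scales every simulated trajectory value by exactly
#' `lambda` (superposition).
#'
#' @param spec An `sd_model`.
#' @param lambda Scale factor.
#' @return The scaled `sd_model`.
#' @export
sd_scale_inputs <- function(spec, lambda) {
  stopifnot(inherits(spec, "sd_model"), is.numeric(lambda), length(lambda) == 1L,
            is.finite(lambda))
  spec$variables <- lapply(spec$variables, function(v) {
    if (v$kind == "constant") {
      v$value <- v$value * lambda
    } else if (v$kind == "auxiliary") {
      v$terms <- lapply(v$terms, function(tm) {
        if (tm$kind == "literal") tm$literal <- tm$literal * lambda
        if (tm$kind == "delay1" && tm$delay$init_policy == "explicit") {
          tm$delay$init_value <- tm$delay$init_value * lambda
        }
        tm
      })
    } else if (v$kind == "stock") {
      v$initial <- v$initial * lambda
    }
    v
  })
  spec
}

#' Replace a constant's value
#'
#' @param spec An `sd_model`.
#' @param name Name of a constant variable.
#' @param value New value.
#' @return The modified `sd_model`.
#' @export
sd_set_constant <- function(spec, name, value) {
  stopifnot(inherits(spec, "sd_model"))
  v <- spec$variables[[name]]
  if (is.null(v)) stop(sprintf("unknown variable '%s'", name))
  if (v$kind != "constant") {
    stop(sprintf("variable '%s' is a %s, not a constant", name, v$kind))
  }
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  spec$variables[[name]]$value <- as.numeric(value)
  spec
}

#' Constant values of a model
#'
#' @param spec An `sd_model`.
#' @return Named numeric vector of constant values, in declaration order.
#' @export
sd_constants <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  vars <- Filter(function(v) v$kind == "constant", spec$variables)
  stats::setNames(vapply(vars, `[[`, numeric(1), "value"),
                  vapply(vars, `[[`, character(1), "name"))
}
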