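# Discrete-time simulation: dependency-ordered algebra, explicit DELAY1 state,
# forward Euler stock integration, and closed-form constant-input asymptotics.

#' Simulation configuration
#'
#' @param t_start,t_end Simulation window in years (defaults 0 and 50).
#' @param dt Integration step in years (default 1); `(t_end - t_start) / dt`
#'   must be a positive integer within rounding tolerance.
#' @param save_every Record every `save_every`-th step (default 1); `t_start`
#'   and `t_end` are always recorded.
#' @return An object of class `sd_config`.
#' @export
sd_config <- function(t_start = 0, t_end = 50, dt = 1, save_every = 1L) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(dt),
            length(t_start) == 1L, length(t_end) == 1L, length(dt) == 1L,
            is.finite(t_start), is.finite(t_end), is.finite(dt))
  if (dt <= 0) stop("dt must be strictly positive")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  n_steps <- (t_end - t_start) / dt
  if (abs(n_steps - round(n_steps)) > 1e-8 * max(1, abs(n_steps))) {
    stop("(t_end - t_start) / dt must be a positive integer")
  }
  save_every <- as.integer(save_every)
  if (is.na(save_every) || save_every < 1L) stop("save_every must be a positive integer")
  structure(list(t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                 dt = as.numeric(dt), save_every = save_every,
                 n_steps = as.integer(round(n_steps))),
            class = "sd_config")
}

#' Initial output of a first-order delay
#'
#' @param delay Delay descriptor as stored in an [sd_delay1()] term: a list
#'   with `delay_time`, `init_policy` and (for the explicit policy)
#'   `init_value`.
#' @param input0 Initial value of the delayed input (used by the equilibrium
#'   policy).
#' @param dt Integration step, used to resolve the `"default"` policy
#'   (zero when `delay_time >= dt`, equilibrium otherwise).
#' @return Initial delay output.
#' @export
delay1_init <- function(delay, input0, dt = 1) {
  policy <- delay$init_policy
  if (policy == "default") {
    policy <- if (delay$delay_time >= dt) "zero" else "equilibrium"
  }
  switch(policy,
         zero = 0,
         equilibrium = input0,
         explicit = delay$init_value,
         stop(sprintf("unknown delay init policy '%s'", policy)))
}

#' Advance a first-order delay by one step
#'
#' The output relaxes towards the input with time constant `delay_time`;
#' `out = input` is an exact fixed point.
#'
#' @param out Current delay output.
#' @param input Current input value.
#' @param delay_time Delay time constant (> 0).
#' @param dt Integration step (> 0).
#' @return Updated delay output `out + (dt / delay_time) * (input - out)`.
#' @export
delay1_step <- function(out, input, delay_time, dt) {
  if (!is.numeric(delay_time) || delay_time <= 0) stop("delay_time must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  out + (dt / delay_time) * (input - out)
}

# Compile a validated model into index-based evaluation plans.
# Returns list(names, kinds, idx, aux_order_idx, plans, delays, stocks, const_idx)
compile_model <- function(spec) {
  nm <- variable_names(spec)
  kinds <- variable_kinds(spec)
  idx <- stats::setNames(seq_along(nm), nm)
  order_names <- sd_dependency_order(spec)

  delays <- list()   # one entry per delay1 term
  plans <- stats::setNames(vector("list", length(nm)), nm)
  for (v in spec$variables) {
    if (v$kind != "auxiliary") next
    lit_sum <- 0
    ref_idx <- integer(0); ref_coef <- numeric(0)
    del_id <- integer(0); del_coef <- numeric(0)
    for (tm in v$terms) {
      if (tm$kind == "literal") {
        lit_sum <- lit_sum + tm$coefficient * tm$literal
      } else if (tm$kind == "ref") {
        ref_idx <- c(ref_idx, idx[[tm$source]])
        ref_coef <- c(ref_coef, tm$coefficient)
      } else {  # delay1
        delays[[length(delays) + 1L]] <- list(
          source_idx = idx[[tm$source]], source = tm$source, host = v$name,
          delay_time = tm$delay$delay_time, init_policy = tm$delay$init_policy,
          init_value = tm$delay$init_value)
        del_id <- c(del_id, length(delays))
        del_coef <- c(del_coef, tm$coefficient)
      }
    }
    plans[[v$name]] <- list(lit = lit_sum, ref_idx = ref_idx, ref_coef = ref_coef,
                            del_id = del_id, del_coef = del_coef)
  }

  stocks <- Filter(function(v) v$kind == "stock", spec$variables)
  list(names = nm, kinds = kinds, idx = idx,
       aux_order = order_names,
       plans = plans, delays = delays,
       stocks = lapply(stocks, function(v)
         list(idx = idx[[v$name]], inflow_idx = idx[[v$inflow]], initial = v$initial)),
       const = Filter(function(v) v$kind == "constant", spec$variables))
}

# Evaluate all auxiliaries in dependency order into `values`, given the
# current delay outputs `delay_out` (numeric vector aligned to cm$delays).
eval_algebra <- function(cm, values, delay_out) {
  for (a in cm$aux_order) {
    p <- cm$plans[[a]]
    x <- p$lit
    if (length(p$ref_idx)) x <- x + sum(p$ref_coef * values[p$ref_idx])
    if (length(p$del_id)) x <- x + sum(p$del_coef * delay_out[p$del_id])
    values[cm$idx[[a]]] <- x
  }
  values
}

# Resolve per-delay init policies under a global override.
resolve_init_policies <- function(cm, dt, init_policy) {
  vapply(cm$delays, function(d) {
    pol <- if (init_policy == "default") d$init_policy else init_policy
    if (pol == "default") pol <- if (d$delay_time >= dt) "zero" else "equilibrium"
    pol
  }, character(1))
}

# Initialize delay outputs. Equilibrium delays need their source's initial
# value, which may depend on other delay outputs: process auxiliaries in a
# combined (ref + equilibrium-delay) topological order.
init_delay_state <- function(cm, values, policies) {
  n_del <- length(cm$delays)
  delay_out <- numeric(n_del)
  needs_input <- logical(n_del)
  for (i in seq_len(n_del)) {
    d <- cm$delays[[i]]
    delay_out[i] <- switch(policies[i],
                           zero = 0,
                           explicit = d$init_value,
                           equilibrium = { needs_input[i] <- TRUE; NA_real_ })
  }
  if (!any(needs_input)) return(delay_out)

  aux_names <- cm$names[cm$kinds == "auxiliary"]
  edges <- list()
  for (a in aux_names) {
    p <- cm$plans[[a]]
    for (j in p$ref_idx) {
      if (cm$kinds[j] == "auxiliary") edges[[length(edges) + 1L]] <- c(cm$names[j], a)
    }
    for (id in p$del_id) {
      if (!needs_input[id]) next
      src <- cm$delays[[id]]$source
      if (cm$kinds[cm$idx[[src]]] == "auxiliary") {
        edges[[length(edges) + 1L]] <- c(src, a)
      }
    }
  }
  ts <- topo_sort_stable(aux_names, edges)
  if (is.null(ts$order)) {
    stop("equilibrium delay initialisation requires acyclic reference + delay dependencies; ",
         sprintf("cycle among {%s}", paste(sort(ts$cycle), collapse = ", ")))
  }
  for (a in ts$order) {
    p <- cm$plans[[a]]
    # fix any equilibrium delays feeding this auxiliary first
    for (id in p$del_id) {
      if (needs_input[id] && is.na(delay_out[id])) {
        delay_out[id] <- values[cm$delays[[id]]$source_idx]
      }
    }
    x <- p$lit
    if (length(p$ref_idx)) x <- x + sum(p$ref_coef * values[p$ref_idx])
    if (length(p$del_id)) x <- x + sum(p$del_coef * delay_out[p$del_id])
    values[cm$idx[[a]]] <- x
  }
  # delays whose source is a constant or stock
  for (i in which(needs_input & is.na(delay_out))) {
    delay_out[i] <- values[cm$delays[[i]]$source_idx]
  }
  delay_out
}

#' Simulate a model
#'
#' Advances the model from `t_start` to `t_end` in steps of `dt`. Each step:
#' (1) evaluates the auxiliaries in dependency order from the current delay
#' outputs and stock values; (2) advances every delay output with
#' [delay1_step()] using the just-evaluated input; (3) advances every stock by
#' explicit Euler, `stock <- stock + dt * inflow`. Values recorded at
#' `t_start` reflect the initial state before any step.
#'
#' @param spec A validated `sd_model` (see [sd_validate()]).
#' @param config An [sd_config()].
#' @param init_policy Global delay initialisation override: `"default"` uses
#'   each delay's declared policy; `"zero"` or `"equilibrium"` force that
#'   policy on every delay.
#' @return An object of class `sd_trajectory`: list with `times` (save grid)
#'   and `values` (matrix, one column per model variable).
#' @export
sd_simulate <- function(spec, config = sd_config(),
                        init_policy = c("default", "zero", "equilibrium")) {
  stopifnot(inherits(spec, "sd_model"), inherits(config, "sd_config"))
  init_policy <- match.arg(init_policy)
  issues <- sd_validate(spec)
  if (length(issues)) {
    stop("invalid model:\n", paste("-", issues, collapse = "\n"))
  }
  if (sum(variable_kinds(spec) == "stock") < 1L) {
    stop("model must declare at least one stock to be simulated")
  }

  cm <- compile_model(spec)
  n_var <- length(cm$names)
  dt <- config$dt

  values <- numeric(n_var)
  for (v in cm$const) values[cm$idx[[v$name]]] <- v$value
  for (s in cm$stocks) values[s$idx] <- s$initial

  policies <- resolve_init_policies(cm, dt, init_policy)
  delay_out <- init_delay_state(cm, values, policies)

  save_idx <- unique(c(seq(0L, config$n_steps, by = config$save_every), config$n_steps))
  times <- config$t_start + save_idx * dt
  out <- matrix(NA_real_, nrow = length(times), ncol = n_var,
                dimnames = list(NULL, cm$names))
  row <- 1L

  delay_T <- vapply(cm$delays, `[[`, numeric(1), "delay_time")
  delay_src <- vapply(cm$delays, `[[`, numeric(1), "source_idx")

  for (k in 0:config$n_steps) {
    values <- eval_algebra(cm, values, delay_out)
    if (!all(is.finite(values))) {
      bad <- cm$names[which(!is.finite(values))[1]]
      stop(sprintf("non-finite value for variable '%s' at step %d (t = %g)",
                   bad, k, config$t_start + k * dt))
    }
    if (k %in% save_idx) {
      out[row, ] <- values
      row <- row + 1L
    }
    if (k < config$n_steps) {
      if (length(delay_out)) {
        delay_out <- delay_out + (dt / delay_T) * (values[delay_src] - delay_out)
      }
      for (s in cm$stocks) values[s$idx] <- values[s$idx] + dt * values[s$inflow_idx]
    }
  }

  structure(list(times = times, values = out,
                 kinds = stats::setNames(cm$kinds, cm$names),
                 config = config, init_policy = init_policy),
            class = "sd_trajectory")
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("<sd_trajectory> %d variables x %d save points, t in [%g, %g]\n",
              ncol(x$values), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one variable's series from a trajectory
#'
#' @param traj An `sd_trajectory`.
#' @param variable Variable name.
#' @return Numeric vector aligned to `traj$times`.
#' @export
sd_series <- function(traj, variable) {
  stopifnot(inherits(traj, "sd_trajectory"))
  if (!variable %in% colnames(traj$values)) {
    stop(sprintf("unknown variable '%s'", variable))
  }
  traj$values[, variable]
}

#' Value of a variable at a save time
#'
#' @param traj An `sd_trajectory`.
#' @param variable Variable name.
#' @param t Time on the save grid.
#' @return Scalar value.
#' @export
sd_at <- function(traj, variable, t) {
  i <- match_time(traj, t)
  sd_series(traj, variable)[i]
}

match_time <- function(traj, t, tol = 1e-8) {
  i <- which(abs(traj$times - t) <= tol * max(1, abs(t)))
  if (length(i) != 1L) stop(sprintf("time %g is not on the save grid", t))
  i
}

#' Tidy data frame of a trajectory
#'
#' Long (time, variable, value) layout: time-major, variables in declaration
#' order within each time.
#'
#' @param x An `sd_trajectory`.
#' @param ... Unused.
#' @return A data frame with columns `time`, `variable`, `value`.
#' @export
as.data.frame.sd_trajectory <- function(x, ...) {
  nm <- colnames(x$values)
  data.frame(time = rep(x$times, each = length(nm)),
             variable = rep(nm, times = length(x$times)),
             value = as.vector(t(x$values)),
             stringsAsFactors = FALSE)
}

#' Constant-input asymptotic values
#'
#' For constant inputs every first-order delay output tends to its input, so
#' the long-run value of each auxiliary is obtained by replacing delay terms
#' with pass-through references and solving the (acyclic) linear algebra once.
#' Stocks are excluded: they grow without bound whenever their flow asymptote
#' is nonzero.
#'
#' @param spec A validated `sd_model`. No auxiliary may depend (directly or
#'   through delays) on a stock, and the combined reference + delay graph must
#'   be acyclic; otherwise an error is raised.
#' @return Named numeric vector of asymptotes for all constants and
#'   auxiliaries, in declaration order.
#' @export
sd_asymptotics <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  issues <- sd_validate(spec)
  if (length(issues)) {
    stop("invalid model:\n", paste("-", issues, collapse = "\n"))
  }
  cm <- compile_model(spec)
  aux_names <- cm$names[cm$kinds == "auxiliary"]
  stock_names <- cm$names[cm$kinds == "stock"]

  # combined graph: ref and delay edges both count as dependencies
  edges <- list()
  for (a in aux_names) {
    p <- cm$plans[[a]]
    parents <- c(cm$names[p$ref_idx],
                 vapply(cm$delays[p$del_id], `[[`, character(1), "source"))
    for (src in parents) {
      if (src %in% stock_names) {
        stop(sprintf(
          "asymptote undefined: auxiliary '%s' depends on stock '%s'", a, src))
      }
      if (src %in% aux_names) edges[[length(edges) + 1L]] <- c(src, a)
    }
  }
  ts <- topo_sort_stable(aux_names, edges)
  if (is.null(ts$order)) {
    stop(sprintf("reference + delay substitution graph is cyclic: {%s}",
                 paste(sort(ts$cycle), collapse = ", ")))
  }

  values <- stats::setNames(numeric(length(cm$names)), cm$names)
  for (v in cm$const) values[[v$name]] <- v$value
  for (a in ts$order) {
    p <- cm$plans[[a]]
    x <- p$lit
    if (length(p$ref_idx)) x <- x + sum(p$ref_coef * values[p$ref_idx])
    for (j in seq_along(p$del_id)) {
      x <- x + p$del_coef[j] * values[[cm$delays[[p$del_id[j]]]$source]]
    }
    values[[a]] <- x
  }
  values[cm$names[cm$kinds != "stock"]]
}
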