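# Steady-state computation: stiff integration to the attractor, then a
# Newton polish on the moiety-reduced system.

# Compile the model's rate vector into a single generated R function (from
# the symbolic transcriptions, constants inlined) for fast repeated
# evaluation inside the integrator and Newton loops.  The generated
# function is verified against the reference evaluators at the model's
# initial state before use, so the numeric rate-law implementations remain
# authoritative.
.compile_rates <- function(model) {
  sp <- c(names(model$initial), names(model$fixed))
  exprs <- vapply(model$reactions, function(r)
    paste(deparse(rate_expression(r$kinetics), width.cutoff = 500L),
          collapse = " "), character(1))
  src <- paste0("function(", paste(sp, collapse = ", "), ") c(",
                paste(sprintf("`%s` = %s", names(exprs), exprs),
                      collapse = ", "), ")")
  f <- compiler::cmpfun(eval(str2lang(src)))
  fx <- as.list(model$fixed)
  fast <- function(conc) do.call(f, c(as.list(pmax(conc, 0)), fx))
  v_ref <- model_rates(model, model$initial, clamp = TRUE)
  v_fast <- fast(model$initial)
  if (max(abs(v_ref - v_fast)) > 1e-8 * max(1, max(abs(v_ref))))
    stop("internal error: compiled rate function disagrees with the ",
         "reference rate laws")
  fast
}

# independent species after eliminating one dependent species per conserved
# moiety (ADP from the adenylate pool, NADH from the nicotinamide pool)
.reduced_sets <- function(model) {
  dep <- character(0)
  if ("adenylate" %in% names(model$totals)) dep <- c(dep, "ADP")
  if ("nicotinamide" %in% names(model$totals)) dep <- c(dep, "NADH")
  dep <- intersect(dep, names(model$initial))
  list(dep = dep, ind = setdiff(names(model$initial), dep))
}

# reconstruct the full state from the independent part using pool totals
.full_state <- function(model, ind_conc) {
  y <- model$initial
  y[names(ind_conc)] <- ind_conc
  if ("adenylate" %in% names(model$totals))
    y["ADP"] <- model$totals[["adenylate"]] - y[["ATP"]]
  if ("nicotinamide" %in% names(model$totals))
    y["NADH"] <- model$totals[["nicotinamide"]] - y[["NAD"]]
  y
}

#' Integrate a model to steady state
#'
#' Integrates dS/dt = N v(S) with a stiff solver (`deSolve::lsoda`) over
#' doubling time horizons until the scaled derivative norm
#' max |dS/dt| / max(|S|, 1 mM) falls below `tol`, then applies a Newton
#' polish on the moiety-reduced system ([refine_newton()]).  Diagnostics are
#' returned either way, with a `converged` flag.
#'
#' @param model a `glyco_model`.
#' @param y0 optional starting concentrations (defaults to the model's
#'   initial state); useful for warm starts along a parameter scan.
#' @param t_max maximum total integration time (model time units).
#' @param tol convergence tolerance on the scaled derivative norm.
#' @param polish apply the Newton refinement after integration.
#' @return object of class `glyco_steady_state`: concentrations (free and
#'   fixed), per-reaction `fluxes`, `pathway_flux` (the lactate-producing
#'   flux), `converged`, `residual`, `method`, `time_integrated`.
#' @export
integrate_to_steady_state <- function(model, y0 = NULL, t_max = 1e6,
                                      tol = 1e-9, polish = TRUE) {
  y <- if (is.null(y0)) model$initial else y0[names(model$initial)]
  N <- stoich_matrix(model)
  fastv <- .compile_rates(model)
  rhs <- function(t, y, parms) {
    list(drop(N %*% fastv(y)))
  }
  scaled_norm <- function(y) {
    d <- drop(N %*% fastv(y))
    max(abs(d) / pmax(abs(y), 1))
  }
  t_span <- 100
  t_total <- 0
  repeat {
    sol <- try(suppressWarnings(
      deSolve::lsoda(y, c(0, t_span), rhs, parms = NULL,
                     rtol = 1e-7, atol = 1e-9, maxsteps = 20000)),
      silent = TRUE)
    if (inherits(sol, "try-error") || anyNA(sol[nrow(sol), -1]) ||
        any(!is.finite(sol[nrow(sol), -1]))) {
      return(.ss_result(model, y, converged = FALSE,
                        method = "lsoda (integration failure)",
                        time_integrated = t_total))
    }
    y <- sol[nrow(sol), -1]
    y[y < 0] <- 0
    t_total <- t_total + t_span
    # a Newton attempt after every span: cheap, and the log-space variant
    # can close in from mid-trajectory states long before the integrator
    # crosses slow manifolds
    if (polish) {
      pol <- refine_newton(model, y)
      if (pol$converged) {
        pol$time_integrated <- t_total
        return(pol)
      }
    }
    if (scaled_norm(y) < tol || t_total >= t_max) break
    t_span <- t_span * 3
  }
  .ss_result(model, y, converged = scaled_norm(y) < tol,
             method = "lsoda", time_integrated = t_total)
}

.ss_result <- function(model, y, converged, method, time_integrated = NA) {
  y <- pmax(y, 0)
  fluxes <- model_rates(model, y, clamp = TRUE)
  N <- stoich_matrix(model)
  d <- drop(N %*% fluxes)
  structure(list(
    concentrations = y,
    fixed = model$fixed,
    fluxes = fluxes,
    pathway_flux = unname(fluxes[model$flux_reaction]),
    residual = max(abs(d) / pmax(abs(y), 1)),
    converged = converged,
    method = method,
    time_integrated = time_integrated
  ), class = "glyco_steady_state")
}

#' Newton refinement of a steady-state estimate
#'
#' Solves N v(S) = 0 on the moiety-reduced system (dependent pool species
#' eliminated through the conserved totals) by damped Newton iteration with
#' a finite-difference Jacobian.  If the Jacobian is singular or the
#' iteration leaves the positive orthant/does not contract, the input guess
#' is returned with a flag rather than an error.
#'
#' @param model a `glyco_model`.
#' @param guess a `glyco_steady_state` (or named concentration vector) near
#'   the steady state.
#' @param tol convergence tolerance on the scaled derivative norm.
#' @param max_iter maximum Newton iterations.
#' @return a `glyco_steady_state`; `method` records `"newton"` on success,
#'   and `newton_flag` carries the failure reason otherwise.
#' @export
refine_newton <- function(model, guess, tol = 1e-12, max_iter = 50) {
  y0 <- if (inherits(guess, "glyco_steady_state"))
    guess$concentrations else guess[names(model$initial)]
  sets <- .reduced_sets(model)
  ind <- sets$ind
  N <- stoich_matrix(model)
  Nind <- N[ind, , drop = FALSE]
  fastv <- .compile_rates(model)
  fn <- function(x) {
    y <- .full_state(model, stats::setNames(x, ind))
    if (any(y < -1e-9)) return(rep(NA_real_, length(x)))
    drop(Nind %*% fastv(pmax(y, 0)))
  }
  x <- y0[ind]
  fx <- fn(x)
  if (anyNA(fx))
    return(.flagged(model, y0, "initial guess outside feasible region"))
  norm0 <- max(abs(fx) / pmax(abs(x), 1))
  for (it in seq_len(max_iter)) {
    if (max(abs(fx) / pmax(abs(x), 1)) < tol) break
    J <- .num_jacobian(fn, x, fx)
    step <- .pinv_step(J, fx)
    if (is.null(step))
      return(.flagged(model, .full_state(model, stats::setNames(x, ind)),
                      "singular Jacobian"))
    lambda <- 1
    improved <- FALSE
    for (h in 1:12) {
      xn <- x + lambda * step
      if (all(is.finite(xn)) && all(xn > -1e-12)) {
        xn <- pmax(xn, 0)
        fn_new <- fn(xn)
        if (!anyNA(fn_new) &&
            max(abs(fn_new)) < max(abs(fx)) * (1 - 1e-4 * lambda) + 1e-300) {
          x <- xn; fx <- fn_new; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  y <- .full_state(model, stats::setNames(x, ind))
  ok <- max(abs(fx) / pmax(abs(x), 1)) < tol
  if (!ok) {
    # linear Newton failed or stalled: retry in log-concentration space,
    # which is well-conditioned across decades and positivity-preserving
    xl <- .newton_log(fn, x, tol, max_iter = 80)
    if (!is.null(xl)) {
      x <- xl
      fx <- fn(x)
      y <- .full_state(model, stats::setNames(x, ind))
      ok <- max(abs(fx) / pmax(abs(x), 1)) < tol
    }
  }
  res <- .ss_result(model, y, converged = ok, method = "newton")
  if (!ok) {
    # did not reach the polish tolerance; report but keep best state if it
    # at least improved on the input guess
    if (max(abs(fx) / pmax(abs(x), 1)) > norm0)
      return(.flagged(model, y0, "newton did not contract"))
    res$newton_flag <- "newton stalled above tolerance"
  }
  res
}

# damped Newton on z = log(x); returns the solution in linear space or NULL
.newton_log <- function(fn, x0, tol, max_iter = 80) {
  z <- log(pmax(x0, 1e-12))
  g <- function(z) fn(exp(z))
  gz <- g(z)
  if (anyNA(gz)) return(NULL)
  for (it in seq_len(max_iter)) {
    x <- exp(z)
    if (max(abs(gz) / pmax(x, 1)) < tol) return(x)
    J <- matrix(NA_real_, length(z), length(z))
    for (j in seq_along(z)) {      # absolute step: z is on a log scale
      zp <- z; zp[j] <- zp[j] + 1e-6
      J[, j] <- (g(zp) - gz) / 1e-6
    }
    if (anyNA(J)) return(NULL)
    step <- .pinv_step(J, gz)
    if (is.null(step)) return(NULL)
    step <- pmin(pmax(step, -8), 8)   # cap per-iteration decade jumps
    lambda <- 1
    improved <- FALSE
    for (h in 1:15) {
      zn <- z + lambda * step
      gn <- g(zn)
      if (!anyNA(gn) && max(abs(gn)) < max(abs(gz)) * (1 - 1e-4 * lambda) +
          1e-300) {
        z <- zn; gz <- gn; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) return(NULL)
  }
  x <- exp(z)
  if (max(abs(gz) / pmax(x, 1)) < tol) x else NULL
}

# Newton step through an SVD pseudo-inverse: near-singular directions
# (numerically flat residual components) are truncated instead of blowing
# up or aborting the iteration.
.pinv_step <- function(J, f, rcond = 1e-13) {
  sv <- try(svd(J), silent = TRUE)
  if (inherits(sv, "try-error")) return(NULL)
  keep <- sv$d > rcond * max(sv$d)
  if (!any(keep)) return(NULL)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% (-f)) / sv$d[keep]))
}

.flagged <- function(model, y, flag) {
  res <- .ss_result(model, y, converged = FALSE, method = "newton")
  res$newton_flag <- flag
  res
}

.num_jacobian <- function(fn, x, fx = NULL, rel = 1e-7) {
  if (is.null(fx)) fx <- fn(x)
  n <- length(x)
  J <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    h <- rel * max(abs(x[j]), 1e-4)
    xp <- x; xp[j] <- x[j] + h
    J[, j] <- (fn(xp) - fx) / h
  }
  J
}

#' Solve a model's steady state
#'
#' Convenience front-end: Newton from the supplied (or model initial) state
#' when it is already near the attractor, falling back to stiff integration
#' plus polish.
#'
#' @inheritParams integrate_to_steady_state
#' @param warm_start optional `glyco_steady_state` or concentration vector
#'   used as the first Newton guess (typical along titration scans).
#' @return a `glyco_steady_state`.
#' @export
steady_state <- function(model, warm_start = NULL, t_max = 1e6, tol = 1e-9) {
  if (!is.null(warm_start)) {
    polished <- refine_newton(model, warm_start)
    if (polished$converged && all(polished$concentrations >= 0))
      return(polished)
  }
  integrate_to_steady_state(model, t_max = t_max, tol = tol)
}

#' @export
print.glyco_steady_state <- function(x, ...) {
  cat("<glyco_steady_state>",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(residual %.3g, %s)\n", x$residual, x$method))
  cat("  pathway flux:", signif(x$pathway_flux, 6), "\n")
  cat("  concentrations (mM):\n")
  print(round(x$concentrations, 5))
  invisible(x)
}

#' Serialize a steady state to a data frame
#' @param ss a `glyco_steady_state`.
#' @return data.frame with species, concentration, and per-reaction fluxes.
#' @export
steady_state_table <- function(ss) {
  data.frame(
    quantity = c(paste0("conc_", names(ss$concentrations)),
                 paste0("flux_", names(ss$fluxes)), "pathway_flux"),
    value = c(unname(ss$concentrations), unname(ss$fluxes),
              ss$pathway_flux),
    stringsAsFactors = FALSE)
}
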