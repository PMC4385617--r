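#' Sigmoid calibration of decision values
#'
#' Maps SVM decision values (margins) \eqn{\phi} to link probabilities through
#' the two-parameter sigmoid \eqn{p(y = +1 \mid \phi) = 1/(1 + e^{A\phi + B})}.
#' With binary targets \eqn{t_l = (y_l + 1)/2 \in \{0, 1\}}, the parameters
#' minimize the cross-entropy
#' \eqn{-\sum_l t_l \log p_l + (1 - t_l) \log(1 - p_l)}
#' via Levenberg–Marquardt damped Newton steps: the logistic Hessian is
#' positive semidefinite, so the damped system
#' \eqn{(H + \mu \,\mathrm{diag}\,H)\,\delta = -g} always yields a descent
#' direction; the damping factor is multiplied by 10 on a rejected step and
#' divided by 10 on an accepted one (start `1e-3`).
#'
#' Targets are the raw `{0, 1}` labels by default. `platt_targets = TRUE`
#' switches to Platt's regularized targets
#' \eqn{t_+ = (N_+ + 1)/(N_+ + 2)}, \eqn{t_- = 1/(N_- + 2)}, which keep the
#' optimum finite on separable data.
#'
#' @param phi numeric vector of decision values.
#' @param labels vector in `{-1, +1}`; both classes required.
#' @param platt_targets use Platt's regularized targets instead of raw 0/1.
#' @param max_iter iteration cap (default 200).
#' @param grad_tol convergence threshold on the gradient infinity norm.
#' @param a_cap bound on `|A|`; perfectly separated margins drive `A` to
#'   infinity, so the fit stops at the cap and sets `capped = TRUE`.
#' @return A list of class `svm_calibration`: `a`, `b_sig`, `n`,
#'   `iterations`, `converged`, `capped`, `cross_entropy`.
#' @examples
#' phi <- c(-2, -1, 1, 2)
#' fit_sigmoid(phi, c(-1, -1, 1, 1), platt_targets = TRUE)
#' @export
fit_sigmoid <- function(phi, labels, platt_targets = FALSE, max_iter = 200L,
                        grad_tol = 1e-8, a_cap = 1e3) {
  y <- as.numeric(labels)
  stopifnot(length(phi) == length(y))
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2) {
    abort("labels must contain both -1 and +1.", class = "kernlink_data_error")
  }
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  t <- if (platt_targets) {
    ifelse(y > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  } else {
    (y + 1) / 2
  }
  # cross-entropy in (A, B); with p = 1/(1+e^z), z = A phi + B:
  # -log p = log(1+e^z) and -log(1-p) = log(1+e^-z)
  nll <- function(a, b) {
    z <- a * phi + b
    sum(t * log1p_exp(z) + (1 - t) * log1p_exp(-z))
  }
  a <- 0
  b <- log(n_neg / n_pos)
  f <- nll(a, b)
  mu <- 1e-3
  it <- 0L
  converged <- FALSE
  capped <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    p <- sigmoid_neg(a * phi + b)
    # d nll / dz = t - p (p decreases in z), Hessian weight p(1-p)
    r <- t - p
    g <- c(sum(r * phi), sum(r))
    if (max(abs(g)) <= grad_tol) { converged <- TRUE; break }
    w <- p * (1 - p)
    H <- matrix(c(sum(w * phi^2), sum(w * phi), sum(w * phi), sum(w)), 2)
    step_ok <- FALSE
    for (damp in 1:50) {
      Hd <- H + mu * diag(pmax(diag(H), 1e-12))
      delta <- tryCatch(solve(Hd, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        a_new <- a + delta[1]; b_new <- b + delta[2]
        f_new <- nll(a_new, b_new)
        if (is.finite(f_new) && f_new <= f) {
          a <- a_new; b <- b_new; f <- f_new
          mu <- mu / 10
          step_ok <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    if (!step_ok) break                       # damping exhausted: stationary
    if (abs(a) >= a_cap) {
      a <- sign(a) * a_cap
      capped <- TRUE
      warn("sigmoid slope reached its cap: margins appear perfectly separated.")
      break
    }
  }
  structure(list(a = a, b_sig = b, n = length(phi), iterations = it,
                 converged = converged, capped = capped, cross_entropy = f,
                 platt_targets = platt_targets),
            class = "svm_calibration")
}

# log(1 + e^z) without overflow
log1p_exp <- function(z) {
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- z[pos] + log1p(exp(-z[pos]))
  out[!pos] <- log1p(exp(z[!pos]))
  out
}

#' Link probabilities from a calibration
#'
#' Evaluates \eqn{p(y = +1 \mid \phi) = 1/(1 + e^{A\phi + B})} in a
#' numerically stable form; outputs lie strictly inside `(0, 1)` up to
#' floating-point rounding.
#'
#' @param cal an `svm_calibration`.
#' @param phi numeric vector of decision values.
#' @return Probability vector aligned with `phi`.
#' @export
predict_proba <- function(cal, phi) {
  stopifnot(inherits(cal, "svm_calibration"))
  sigmoid_neg(cal$a * phi + cal$b_sig)
}

# 1/(1+e^z) without overflow for large |z|
sigmoid_neg <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- exp(-z[pos]) / (1 + exp(-z[pos]))
  out[!pos] <- 1 / (1 + exp(z[!pos]))
  out
}

#' @export
print.svm_calibration <- function(x, ...) {
  cat(sprintf("<svm_calibration: A = %.4g, B = %.4g (n = %d, %s)>\n",
              x$a, x$b_sig, x$n,
              if (x$capped) "slope capped"
              else if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' @method tidy svm_calibration
#' @export
tidy.svm_calibration <- function(x, ...) {
  tibble::tibble(term = c("A", "B"), estimate = c(x$a, x$b_sig))
}

#' @method glance svm_calibration
#' @export
glance.svm_calibration <- function(x, ...) {
  tibble::tibble(n = x$n, cross_entropy = x$cross_entropy,
                 iterations = x$iterations, converged = x$converged,
                 capped = x$capped)
}
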