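#' Model hyperparameters for the rate distributions
#'
#' The omega (dN/dS) distribution has `n_omega` bins ordered
#' `w1 <= ... <= w_{N-2} <= 1 <= w_{N-1}`; with the error sink enabled an
#' extra bin is constrained to `omega_N >= E` with weight at most `p_e_max`.
#' The synonymous-rate distribution has `m_alpha` bins constrained to unit
#' mean.  Defaults follow the BUSTED-E model: N = 4 (two
#' purifying/neutral classes, one selection class, one error sink), M = 3,
#' E = 100, maximum error weight 1%.
#'
#' @param n_omega Number of omega bins including the error sink (default 4).
#' @param m_alpha Number of synonymous rate bins (default 3).
#' @param error_sink Include the error-sink class (default TRUE).
#' @param E Lower bound of the error-sink omega (default 100).
#' @param p_e_max Maximum weight of the error-sink class (default 0.01).
#' @param variant `"alternative"` or `"null"`; the null fixes the selection
#'   class at omega = 1 for the EDS likelihood-ratio test.
#' @export
model_hyper <- function(n_omega = 4, m_alpha = 3, error_sink = TRUE,
                        E = 100, p_e_max = 0.01,
                        variant = c("alternative", "null")) {
  variant <- match.arg(variant)
  if (error_sink) {
    stopifnot(n_omega >= 2, E > 1, p_e_max > 0, p_e_max <= 1)
  } else {
    stopifnot(n_omega >= 1)
  }
  structure(list(n_omega = as.integer(n_omega), m_alpha = as.integer(m_alpha),
                 error_sink = error_sink, E = E, p_e_max = p_e_max,
                 variant = variant),
            class = "model_hyper")
}

# number of biological (non-sink) omega classes
n_bio_classes <- function(hyper) hyper$n_omega - as.integer(hyper$error_sink)

#' Validate a pair of rate distributions against the model constraints
#'
#' @param dist List with `omega = list(rates, weights)` and
#'   `alpha = list(rates, weights)`.
#' @param hyper A [model_hyper()] object.
#' @param tol Numerical tolerance.
#' @return Invisibly TRUE; errors otherwise.
#' @export
validate_distributions <- function(dist, hyper, tol = 1e-9) {
  om <- dist$omega; al <- dist$alpha
  nb <- n_bio_classes(hyper)
  stopifnot(length(om$rates) == hyper$n_omega,
            length(om$weights) == hyper$n_omega,
            length(al$rates) == hyper$m_alpha,
            length(al$weights) == hyper$m_alpha)
  if (any(om$rates < 0) || any(om$weights < -tol))
    stop("negative omega rate or weight")
  if (abs(sum(om$weights) - 1) > tol) stop("omega weights do not sum to 1")
  if (abs(sum(al$weights) - 1) > tol) stop("alpha weights do not sum to 1")
  if (abs(sum(al$rates * al$weights) - 1) > tol)
    stop("alpha distribution does not have unit mean")
  if (is.unsorted(al$rates, strictly = FALSE)) stop("alpha rates not ordered")
  if (nb >= 2 && is.unsorted(om$rates[seq_len(nb - 1)]))
    stop("omega rates not ordered")
  if (nb >= 2 && om$rates[nb - 1] > 1 + tol)
    stop("sub-neutral omega class exceeds 1")
  # the selection-class bounds only exist once there are >= 2 biological
  # classes (a single-class model is the unconstrained MG94 mean fit)
  if (nb >= 2 && om$rates[nb] < 1 - tol && hyper$variant == "alternative")
    stop("selection-class omega below 1")
  if (nb >= 2 && hyper$variant == "null" && abs(om$rates[nb] - 1) > tol)
    stop("null variant requires the selection class fixed at omega = 1")
  if (hyper$error_sink) {
    if (om$rates[hyper$n_omega] < hyper$E - tol)
      stop("error-sink omega below its bound E")
    if (om$weights[hyper$n_omega] > hyper$p_e_max + tol)
      stop("error-sink weight exceeds its cap")
  }
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
softmax1 <- function(v) { e <- exp(c(v, 0) - max(v, 0)); e / sum(e) }

# ---- unconstrained <-> constrained transforms -------------------------------
#
# omega (alternative, sink):  u = (u1, u2, u3, u4, v1, v2, v3)
#   w2 = plogis(u2); w1 = w2 plogis(u1); w3 = 1 + exp(u3); w4 = E + exp(u4)
#   p4 = p_e_max plogis(v3); (p1,p2,p3) = (1 - p4) softmax(v1, v2, 0)
# null drops u3 (w3 = 1); no sink drops u4, v3.
#
# alpha (M bins): pre-rates r1 = plogis(a1), r2 = 1, r_j = r_{j-1} + exp(a_j);
# weights softmax; rates normalized by their mean (unit-mean constraint).

n_free_omega <- function(hyper) {
  nb <- n_bio_classes(hyper)
  nrates <- (nb - 1) + (hyper$variant == "alternative") + hyper$error_sink
  nweights <- (nb - 1) + hyper$error_sink
  c(rates = nrates, weights = nweights)
}

unpack_omega <- function(u, hyper) {
  nb <- n_bio_classes(hyper)
  i <- 0
  rates <- numeric(0)
  if (nb >= 2) {
    w2 <- stats::plogis(u[i + nb - 1])
    low <- w2
    if (nb > 2) {
      # cumulative logistic products keep w1 <= ... <= w_{nb-1}
      low <- numeric(nb - 1)
      low[nb - 1] <- w2
      for (j in (nb - 2):1) low[j] <- low[j + 1] * stats::plogis(u[i + j])
    }
    rates <- low
    i <- i + nb - 1
  }
  # selection and sink rates are capped at 1e4 above their lower bounds:
  # transition probabilities saturate near the stationary row well before
  # that, so larger values are likelihood-indistinguishable but numerically
  # hazardous
  if (hyper$variant == "alternative") {
    rates <- c(rates, 1 + exp(clamp(u[i + 1], -700, log(1e4))))
    i <- i + 1
  } else {
    rates <- c(rates, 1)
  }
  if (hyper$error_sink) {
    rates <- c(rates, hyper$E + exp(clamp(u[i + 1], -700, log(1e4))))
    i <- i + 1
  }
  if (nb >= 2) {
    base <- softmax1(u[i + seq_len(nb - 1)])
    i <- i + nb - 1
  } else base <- 1
  if (hyper$error_sink) {
    p4 <- hyper$p_e_max * stats::plogis(u[i + 1])
    i <- i + 1
    weights <- c((1 - p4) * base, p4)
  } else {
    weights <- base
  }
  list(rates = rates, weights = weights)
}

pack_omega <- function(om, hyper, big = 30) {
  nb <- n_bio_classes(hyper)
  u <- numeric(0)
  if (nb >= 2) {
    r <- om$rates[seq_len(nb - 1)]
    uu <- numeric(nb - 1)
    uu[nb - 1] <- stats::qlogis(clamp(r[nb - 1], 1e-12, 1 - 1e-12))
    if (nb > 2)
      for (j in (nb - 2):1)
        uu[j] <- stats::qlogis(clamp(r[j] / max(r[j + 1], 1e-12), 1e-12, 1 - 1e-12))
    u <- clamp(uu, -big, big)
  }
  if (hyper$variant == "alternative")
    u <- c(u, clamp(log(max(om$rates[nb] - 1, 1e-13)), -big, big))
  if (hyper$error_sink)
    u <- c(u, clamp(log(max(om$rates[hyper$n_omega] - hyper$E, 1e-13)), -big, big))
  w <- om$weights
  if (hyper$error_sink) {
    p4 <- w[hyper$n_omega]
    base <- w[seq_len(nb)] / max(1 - p4, 1e-12)
    if (nb >= 2)
      u <- c(u, clamp(log(base[seq_len(nb - 1)] / max(base[nb], 1e-300)), -big, big))
    u <- c(u, clamp(stats::qlogis(clamp(p4 / hyper$p_e_max, 1e-12, 1 - 1e-12)), -big, big))
  } else if (nb >= 2) {
    u <- c(u, clamp(log(w[seq_len(nb - 1)] / max(w[nb], 1e-300)), -big, big))
  }
  u
}

unpack_alpha <- function(u, M) {
  if (M == 1) return(list(rates = 1, weights = 1))
  a <- u[seq_len(M - 1)]
  w <- u[M - 1 + seq_len(M - 1)]
  r <- numeric(M)
  r[1] <- stats::plogis(a[1])
  r[2] <- 1
  if (M > 2) for (j in 3:M) r[j] <- r[j - 1] + exp(clamp(a[j - 1], -700, 700))
  q <- softmax1(w)
  m <- sum(q * r)
  list(rates = r / m, weights = q)
}

pack_alpha <- function(al, big = 30) {
  M <- length(al$rates)
  if (M == 1) return(numeric(0))
  r <- al$rates / al$rates[2]  # anchor the second pre-rate at 1
  a <- numeric(M - 1)
  a[1] <- clamp(stats::qlogis(clamp(r[1], 1e-12, 1 - 1e-12)), -big, big)
  if (M > 2)
    for (j in 3:M) a[j - 1] <- clamp(log(max(r[j] - r[j - 1], 1e-13)), -big, big)
  q <- al$weights
  c(a, clamp(log(q[seq_len(M - 1)] / max(q[M], 1e-300)), -big, big))
}

pack_dist <- function(dist, hyper) {
  c(pack_omega(dist$omega, hyper), pack_alpha(dist$alpha))
}

unpack_dist <- function(u, hyper) {
  no <- sum(n_free_omega(hyper))
  list(omega = unpack_omega(u[seq_len(no)], hyper),
       alpha = unpack_alpha(u[-seq_len(no)], hyper$m_alpha))
}

n_free_dist <- function(hyper) {
  sum(n_free_omega(hyper)) + 2 * (hyper$m_alpha - 1)
}

# ---- Latin hypercube starting points ---------------------------------------

#' Propose mean-constrained starting distributions by Latin hypercube sampling
#'
#' Draws `K` joint (omega, alpha) distributions whose omega mean equals the
#' single-class estimate `omega0` and whose alpha mean is 1, honoring all
#' ordering and error-sink bound constraints.  The selection-class rate is
#' solved from the mean constraint; draws for which no valid solution exists
#' are redrawn (up to 100 times per slot).
#'
#' @param K Number of draws.
#' @param omega0 Target mean of the omega distribution (phase-3 estimate).
#' @param hyper A [model_hyper()] object.
#' @param seed RNG seed; identical seeds give identical draws.
#' @return List of `K` distribution lists (`omega`, `alpha`).
#' @export
propose_starts <- function(K, omega0, hyper, seed = 1) {
  stopifnot(K >= 1, omega0 > 0)
  with_local_seed(seed, {
    d <- if (hyper$error_sink) 6 else 4
    d <- d + 2 * (hyper$m_alpha > 1)
    H <- lhs::randomLHS(K, max(d, 2))
    lapply(seq_len(K), function(i) {
      draw <- try_draw(H[i, ], omega0, hyper)
      tries <- 0
      while (is.null(draw)) {
        tries <- tries + 1
        if (tries > 100)
          stop("could not draw a feasible start for omega0 = ", omega0)
        draw <- try_draw(stats::runif(ncol(H)), omega0, hyper)
      }
      draw
    })
  })
}

# map one uniform vector to a feasible (omega, alpha) draw, or NULL
try_draw <- function(u, omega0, hyper) {
  nb <- n_bio_classes(hyper)
  i <- 1
  if (hyper$error_sink) {
    w4 <- hyper$E * (1 + 9 * u[i]); i <- i + 1
    p4 <- u[i] * min(hyper$p_e_max, 0.5 * omega0 / w4); i <- i + 1
  } else {
    w4 <- NULL; p4 <- 0
  }
  budget <- omega0 - p4 * (w4 %||% 0)
  s1 <- u[i]; s2 <- u[i + 1]; i <- i + 2
  base <- c(s1, (1 - s1) * s2, (1 - s1) * (1 - s2))  # stick-breaking
  if (nb == 2) base <- c(s1, 1 - s1)
  pbio <- (1 - p4) * base
  w2 <- u[i] * min(1, 2 * budget); i <- i + 1
  w1 <- u[i] * w2; i <- i + 1
  # selection-class rate solved from the mean constraint; draws whose
  # solved rate exceeds 50 are rejected as near-degenerate with the
  # error sink (transition probabilities saturate)
  lowmass <- if (nb >= 3) pbio[1] * w1 + pbio[2] * w2 else pbio[1] * w1
  wsel <- (budget - lowmass) / pbio[nb]
  if (!is.finite(wsel) || wsel < 1 || wsel > 50) return(NULL)
  om <- if (nb >= 3) list(rates = c(w1, w2, wsel), weights = pbio)
        else list(rates = c(w1, wsel), weights = pbio)
  if (hyper$error_sink) {
    om$rates <- c(om$rates, w4)
    om$weights <- c(om$weights, p4)
  }
  M <- hyper$m_alpha
  if (M == 1) {
    al <- list(rates = 1, weights = 1)
  } else {
    a2 <- u[i]; a1 <- u[i + 1] * a2
    t1 <- stats::runif(1); t2 <- stats::runif(1)
    q <- if (M == 2) c(t1, 1 - t1) else c(t1, (1 - t1) * t2, (1 - t1) * (1 - t2))
    r <- if (M == 2) c(a1, NA) else c(a1, a2, NA)
    r[M] <- (1 - sum(q[-M] * r[-M])) / q[M]
    if (r[M] < r[M - 1]) return(NULL)
    al <- list(rates = r, weights = q)
  }
  list(omega = om, alpha = al)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expressions under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
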