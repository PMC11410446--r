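#' Specify a minimax order-reduction problem
#'
#' The reduction seeks a low-order digital transfer function whose magnitude
#' response stays as close as possible to a high-order prototype, in the
#' minimax (Chebyshev) sense: the outer problem minimizes, over the reduced
#' filter's coefficient vector, the inner maximum over a frequency grid of
#' the absolute magnitude-response difference. Coefficients are constrained
#' to a nonnegative box, which is what guarantees the reduced filter has no
#' negative coefficients.
#'
#' @param prototype a stable digital [transfer_function()] to approximate.
#' @param num_order target numerator degree (default 1).
#' @param den_order target denominator degree (default 0, i.e. a scalar
#'   denominator).
#' @param grid frequency grid in Hz; default 256 log-spaced points from
#'   0.1 Hz to 99% of Nyquist.
#' @param bounds length-2 numeric box `c(lower, upper)` for every
#'   coefficient; the lower bound is clamped at 0.
#' @param seed integer seed for the optimizer's restarts.
#' @param max_iter Nelder-Mead iteration budget per start.
#' @param tol convergence tolerance on the objective.
#' @return An object of class `reduction_problem`.
#' @export
reduction_problem <- function(prototype, num_order = 1L, den_order = 0L,
                              grid = NULL, bounds = c(0, 5), seed = 1L,
                              max_iter = 1000L, tol = 1e-9) {
  stopifnot(is_transfer_function(prototype))
  if (prototype$domain != "z") {
    stop("order reduction operates on digital prototypes; discretize first",
         call. = FALSE)
  }
  num_order <- as.integer(num_order)
  den_order <- as.integer(den_order)
  proto_order <- filter_order(prototype)
  if (num_order < 0L || den_order < 0L) stop("target orders must be nonnegative", call. = FALSE)
  if (max(num_order, den_order) > proto_order) {
    stop("target order must not exceed the prototype order", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- exp(seq(log(0.1), log(0.99 * prototype$fs / 2), length.out = 256))
  }
  grid <- as.numeric(grid)
  if (length(grid) == 0L || any(diff(grid) <= 0) || any(grid >= prototype$fs / 2)) {
    stop("grid must be nonempty, strictly increasing and below Nyquist", call. = FALSE)
  }
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("'bounds' must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  bounds[1] <- max(bounds[1], 0)
  structure(list(prototype = prototype, num_order = num_order,
                 den_order = den_order, grid = grid, bounds = bounds,
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 tol = tol),
            class = "reduction_problem")
}

#' Maximum magnitude-response deviation between two filters
#'
#' The inner objective of the minimax reduction: the largest absolute
#' difference of magnitude responses over a frequency grid. Symmetric in its
#' two arguments.
#'
#' @param a,b [transfer_function()] objects evaluable on the grid.
#' @param grid numeric vector of frequencies in Hz, nonempty.
#' @return a single nonnegative number.
#' @export
response_deviation <- function(a, b, grid) {
  if (length(grid) == 0L) stop("'grid' must be nonempty", call. = FALSE)
  max(abs(Mod(evaluate_response(a, grid)) - Mod(evaluate_response(b, grid))))
}

# deviation for raw coefficient vectors against precomputed prototype
# magnitudes; z1 = exp(-1i w) on the grid
tap_deviation <- function(num, den, z1, proto_mag) {
  hn <- poly_eval(rev(num), z1)
  hd <- poly_eval(rev(den), z1)
  max(abs(Mod(hn / hd) - proto_mag))
}

project_theta <- function(theta, problem) {
  lo <- problem$bounds[1]; hi <- problem$bounds[2]
  theta <- pmin(pmax(theta, lo), hi)
  # denominator leading coefficient must stay away from zero
  a0_pos <- problem$num_order + 2L
  theta[a0_pos] <- max(theta[a0_pos], 0.05)
  theta
}

theta_split <- function(theta, problem) {
  nb <- problem$num_order + 1L
  list(num = theta[seq_len(nb)], den = theta[(nb + 1L):length(theta)])
}

#' Minimax reduction of a digital IIR transfer function
#'
#' Approximates the prototype's magnitude response with a low-order filter
#' whose coefficients are all nonnegative. The inner maximization (worst
#' frequency) is exact — a scan over the problem's grid; the outer
#' minimization runs Nelder-Mead over the coefficient vector, with every
#' candidate projected onto the nonnegative box before evaluation.
#' Optimization proceeds sequentially through target numerator degrees
#' `0, 1, ..., num_order`, warm-starting each degree from the previous
#' solution padded with a zero, so the achieved deviation is non-increasing
#' in the target order by construction. The first start is seeded by a
#' linear least-squares fit of the prototype's complex response; further
#' seeded random restarts guard against local minima. Unstable candidate
#' denominators are rejected through a penalty.
#'
#' @param problem a [reduction_problem()].
#' @return An object of class `reduction_result` with fields `tf` (the
#'   reduced digital [transfer_function()], all coefficients >= 0),
#'   `deviation` (achieved minimax magnitude deviation), `iterations`,
#'   `converged`, and `order` (the reported reduced-filter order, counted as
#'   the number of coefficients of the longer polynomial, so the default
#'   numerator-degree-1 / scalar-denominator target reports order 2).
#' @examples
#' proto <- design_iir_cascade(fs = 360)
#' res <- minimax_reduce(reduction_problem(proto))
#' res$order          # 2
#' all(res$tf$num >= 0) && all(res$tf$den >= 0)
#' @export
minimax_reduce <- function(problem) {
  stopifnot(inherits(problem, "reduction_problem"))
  set.seed(problem$seed)
  proto <- problem$prototype
  z1 <- exp(-2i * pi * problem$grid / proto$fs)
  proto_mag <- Mod(evaluate_response(proto, problem$grid))
  dd <- problem$den_order
  total_iter <- 0L
  converged <- TRUE

  objective <- function(theta) {
    theta <- project_theta(theta, problem)
    parts <- theta_split(theta, problem)
    if (dd > 0L) {
      # stability: poles of den (taps, descending powers of z) inside unit circle
      r <- polyroot(rev(parts$den))
      excess <- Mod(r) - 1
      if (any(excess >= 0)) return(1e6 + sum(pmax(excess, 0)))
    }
    tap_deviation(parts$num, parts$den, z1, proto_mag)
  }

  ls_seed <- function(nb) {
    # least-squares fit of the complex response with a unit denominator
    basis <- sapply(seq_len(nb) - 1L, function(k) z1^k)
    h <- evaluate_response(proto, problem$grid)
    A <- rbind(Re(basis), Im(basis))
    y <- c(Re(h), Im(h))
    b <- tryCatch(qr.solve(A, y), error = function(e) rep(mean(proto_mag) / nb, nb))
    c(pmax(b, 0), 1, rep(0, dd))
  }

  run_starts <- function(theta0_list) {
    best <- NULL
    for (th0 in theta0_list) {
      th0 <- project_theta(th0, problem)
      f0 <- objective(th0)
      if (is.null(best) || f0 < best$value) {
        best <- list(par = th0, value = f0, counts = c(0, 0), convergence = 0L)
      }
      o <- stats::optim(th0, objective, method = "Nelder-Mead",
                        control = list(maxit = problem$max_iter,
                                       reltol = problem$tol))
      total_iter <<- total_iter + unname(o$counts[1])
      if (o$convergence != 0L) converged <<- FALSE
      if (o$value < best$value) best <- o
    }
    best
  }

  best <- NULL
  for (nn in 0:problem$num_order) {
    sub <- problem
    sub$num_order <- nn
    starts <- list(ls_seed(nn + 1L))
    if (!is.null(best)) {
      # warm start: previous numerator padded with a trailing zero tap
      prev <- theta_split(best$par, sub_prev)
      starts <- c(list(c(prev$num, 0, prev$den)), starts)
    }
    # seeded random restarts
    for (k in 1:3) {
      starts <- c(starts, list(runif(nn + 1L + dd + 1L, 0, mean(problem$bounds))))
    }
    # evaluate objective in the sub-problem geometry
    problem_hold <- problem
    problem <- sub
    best <- run_starts(starts)
    problem <- problem_hold
    sub_prev <- sub
  }

  # final polish + projection in the full-target geometry
  theta <- project_theta(best$par, sub_prev)
  parts <- theta_split(theta, sub_prev)
  dev <- tap_deviation(parts$num, parts$den, z1, proto_mag)
  red <- transfer_function(parts$num, parts$den, domain = "z", fs = proto$fs)
  if (!converged) warning("minimax reduction hit the iteration budget before converging")
  structure(list(tf = red, deviation = dev, iterations = total_iter,
                 converged = converged,
                 order = max(length(parts$num), length(parts$den))),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> order %d, minimax deviation %.5g (%s, %d evaluations)\n",
              x$order, x$deviation,
              if (x$converged) "converged" else "not converged", x$iterations))
  print(x$tf)
  invisible(x)
}
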