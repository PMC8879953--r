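# Mamdani fuzzy inference for the Level-3 diagnosis: fuzzification of the
# behavior-frequency variable, a total rule base over {Seldom, Consistent,
# Most}, min-implication with max aggregation, center-of-gravity
# defuzzification, and a strict threshold decision per behavior.

#' Define fuzzy sets and linguistic variables
#'
#' A linguistic variable is a crisp universe `[lo, hi]` carrying named
#' piecewise-linear fuzzy sets. `trapezoid(a, b, c, d)` rises on `[a, b]`,
#' holds 1 on `[b, c]` and falls on `[c, d]`; `triangle(a, b, c)` is the
#' degenerate trapezoid with `b == c`.
#'
#' @param a,b,c,d Breakpoints, non-decreasing.
#' @return `trapezoid()`/`triangle()`: a breakpoint vector;
#'   `linguistic_variable()`: a `linguistic_variable` object with a
#'   `sets` tibble (`set`, `a`, `b`, `c`, `d`).
#' @examples
#' freq <- linguistic_variable("frequency", c(0, 1),
#'   Seldom = trapezoid(0, 0, 0.15, 0.45),
#'   Consistent = triangle(0.15, 0.45, 0.75),
#'   Most = trapezoid(0.3, 0.45, 1, 1))
#' fuzzify(0.3, freq)
#' @export
trapezoid <- function(a, b, c, d) {
  if (any(diff(c(a, b, c, d)) < 0)) abort("breakpoints must be non-decreasing")
  c(a = a, b = b, c = c, d = d)
}

#' @rdname trapezoid
#' @export
triangle <- function(a, b, c) trapezoid(a, b, b, c)

#' @rdname trapezoid
#' @param name Variable name.
#' @param universe Numeric `c(lo, hi)`, `lo < hi`.
#' @param ... Named fuzzy sets built with [trapezoid()] or [triangle()].
#' @export
linguistic_variable <- function(name, universe, ...) {
  sets <- list(...)
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("supply at least one named fuzzy set")
  }
  if (length(universe) != 2 || universe[1] >= universe[2]) {
    abort("universe must be c(lo, hi) with lo < hi")
  }
  tbl <- purrr::imap_dfr(sets, function(bp, nm) {
    if (bp[["a"]] < universe[1] || bp[["d"]] > universe[2]) {
      abort(paste0("set '", nm, "' breakpoints fall outside the universe"))
    }
    tibble(set = nm, a = bp[["a"]], b = bp[["b"]], c = bp[["c"]], d = bp[["d"]])
  })
  structure(list(name = name, universe = as.numeric(universe), sets = tbl),
            class = "linguistic_variable")
}

#' @export
print.linguistic_variable <- function(x, ...) {
  cat("Linguistic variable '", x$name, "' on [", x$universe[1], ", ",
      x$universe[2], "]\n", sep = "")
  print(x$sets)
  invisible(x)
}

trapezoid_mu <- function(x, a, b, c, d) {
  mu <- numeric(length(x))
  if (b > a) {
    r <- x >= a & x < b
    mu[r] <- (x[r] - a) / (b - a)
  }
  mu[x >= b & x <= c] <- 1
  if (d > c) {
    f <- x > c & x <= d
    mu[f] <- (d - x[f]) / (d - c)
  }
  mu
}

#' Default linguistic variables of the diagnosis engine
#'
#' `default_frequency_variable()` covers the crisp behavior-frequency input
#' on `[0, 1]` with sets Seldom (trapezoid 0, 0, 0.15, 0.45), Consistent
#' (triangle 0.15, 0.45, 0.75) and Most (trapezoid 0.3, 0.45, 1, 1). The
#' Seldom/Consistent crossover is calibrated so a frequency of 0.3 is exactly
#' 50% Seldom and 50% Consistent; Most reaches full membership where Seldom's
#' support ends, which keeps the defuzzified diagnosis index monotone in the
#' frequency (see the methods vignette).
#'
#' `default_diagnosis_variable()` covers the diagnosis index on `[0, 3]` with
#' Normal (trapezoid 0, 0, 0.5, 1.5) and Abnormal (trapezoid 1, 2, 3, 3), so
#' the pure-Normal centroid (~0.542) sits below and the pure-Abnormal
#' centroid (~2.222) above both decision thresholds (1.0, 1.5).
#'
#' @return A [linguistic_variable()].
#' @export
default_frequency_variable <- function() {
  linguistic_variable("frequency", c(0, 1),
                      Seldom = trapezoid(0, 0, 0.15, 0.45),
                      Consistent = triangle(0.15, 0.45, 0.75),
                      Most = trapezoid(0.3, 0.45, 1, 1))
}

#' @rdname default_frequency_variable
#' @export
default_diagnosis_variable <- function() {
  linguistic_variable("diagnosis", c(0, 3),
                      Normal = trapezoid(0, 0, 0.5, 1.5),
                      Abnormal = trapezoid(1, 2, 3, 3))
}

#' Default fuzzy rule base
#'
#' For every symptomatic complex behavior the mapping is identical: Seldom
#' frequency is Normal; Consistent or Most frequency is Abnormal.
#'
#' @return A tibble with columns `behavior`, `input_set`, `output_set`,
#'   total over \{Seldom, Consistent, Most\} for each behavior.
#' @export
default_rule_base <- function() {
  tidyr::expand_grid(behavior = complex_classes(),
                     input_set = c("Seldom", "Consistent", "Most")) |>
    dplyr::mutate(output_set = ifelse(.data$input_set == "Seldom",
                                      "Normal", "Abnormal"))
}

#' Default decision thresholds
#'
#' Heuristic thresholds on the defuzzified diagnosis index: 1.0 for
#' vocalization, 1.5 for destructive and exploratory behavior. An index
#' strictly above the threshold is diagnosed Abnormal.
#'
#' @return Named numeric vector over [complex_classes()].
#' @export
default_thresholds <- function() {
  c(Destructive = 1.5, Exploratory = 1.5, Vocalization = 1.0)
}

#' Bundle a configured fuzzy diagnosis engine
#'
#' @param input [linguistic_variable()] for the frequency input on `[0, 1]`.
#' @param output [linguistic_variable()] for the diagnosis index.
#' @param rule_base Rule tibble as in [default_rule_base()].
#' @param thresholds Named numeric vector of per-behavior decision thresholds,
#'   inside the output universe.
#' @param resolution Center-of-gravity integration step, as a fraction of the
#'   output universe (composite trapezoid rule).
#' @return A `fuzzy_engine` object.
#' @examples
#' eng <- fuzzy_engine()
#' diagnose(c(0, 0.3, 1), "Vocalization", eng)
#' @export
fuzzy_engine <- function(input = default_frequency_variable(),
                         output = default_diagnosis_variable(),
                         rule_base = default_rule_base(),
                         thresholds = default_thresholds(),
                         resolution = 1e-3) {
  stopifnot(resolution > 0, resolution <= 0.1)
  out_sets <- unique(rule_base$output_set)
  if (!all(out_sets %in% output$sets$set)) {
    abort("rule base concludes sets absent from the output variable")
  }
  if (any(thresholds < output$universe[1] | thresholds > output$universe[2])) {
    abort("thresholds must lie within the output universe")
  }
  structure(list(input = input, output = output, rule_base = rule_base,
                 thresholds = thresholds, resolution = resolution),
            class = "fuzzy_engine")
}

#' @export
print.fuzzy_engine <- function(x, ...) {
  cat("Fuzzy diagnosis engine\n",
      "  input: '", x$input$name, "' sets {",
      paste(x$input$sets$set, collapse = ", "), "}\n",
      "  output: '", x$output$name, "' on [", x$output$universe[1], ", ",
      x$output$universe[2], "]\n",
      "  thresholds: ",
      paste(names(x$thresholds), x$thresholds, sep = " > ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Fuzzify a crisp frequency
#'
#' Evaluates every membership function of the input variable at `f`.
#'
#' @param f Frequency fraction(s) in `[0, 1]` (coverage of the observation
#'   window).
#' @param variable Input [linguistic_variable()].
#' @return A tibble with columns `f`, `set`, `degree` (one row per set and
#'   input value).
#' @export
fuzzify <- function(f, variable = default_frequency_variable()) {
  if (any(f < variable$universe[1] | f > variable$universe[2])) {
    abort("frequency outside the input universe")
  }
  f <- as.numeric(f)
  purrr::pmap_dfr(variable$sets, function(set, a, b, c, d) {
    tibble(f = f, set = set, degree = trapezoid_mu(f, a, b, c, d))
  }) |>
    dplyr::arrange(.data$f) |>
    dplyr::select("f", "set", "degree")
}

membership_grid <- function(variable, resolution) {
  lo <- variable$universe[1]
  hi <- variable$universe[2]
  step <- (hi - lo) * resolution
  seq(lo, hi, by = step)
}

#' Mamdani inference: clip and combine output sets
#'
#' Each rule of the behavior's rule base fires at the degree of its input
#' set; an output set is clipped (min-implication) at the maximum activation
#' over rules concluding it, and the clipped sets are combined pointwise by
#' maximum into one aggregated shape on the output universe.
#'
#' @param memberships Fuzzification result for a single crisp input: a tibble
#'   with columns `set` and `degree` (e.g. one value's rows from
#'   [fuzzify()]), or a named numeric vector.
#' @param behavior A complex behavior class present in the rule base.
#' @param engine A [fuzzy_engine()].
#' @return An `aggregated_shape`: tibble with columns `x`, `mu` sampling the
#'   combined membership function.
#' @export
fuzzy_infer <- function(memberships, behavior, engine = fuzzy_engine()) {
  if (is.numeric(memberships)) {
    memberships <- tibble(set = names(memberships),
                          degree = as.numeric(memberships))
  }
  rules <- dplyr::filter(engine$rule_base, .data$behavior == !!behavior)
  if (nrow(rules) == 0) {
    abort(paste0("behavior '", behavior, "' is absent from the rule base"))
  }
  act <- rules |>
    dplyr::left_join(memberships, by = c(input_set = "set")) |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0)) |>
    dplyr::group_by(.data$output_set) |>
    dplyr::summarise(level = max(.data$degree), .groups = "drop")
  x <- membership_grid(engine$output, engine$resolution)
  mu <- numeric(length(x))
  sets <- engine$output$sets
  for (i in seq_len(nrow(act))) {
    bp <- sets[sets$set == act$output_set[i], ]
    mu_set <- pmin(trapezoid_mu(x, bp$a, bp$b, bp$c, bp$d), act$level[i])
    mu <- pmax(mu, mu_set)
  }
  structure(tibble(x = x, mu = mu), class = c("aggregated_shape",
                                              class(tibble())))
}

#' Center-of-gravity defuzzification
#'
#' Collapses an aggregated output shape to its centroid
#' `integral(x mu(x)) / integral(mu(x))` by the composite trapezoid rule on
#' the shape's grid.
#'
#' @param shape An `aggregated_shape` from [fuzzy_infer()], or any tibble
#'   with numeric columns `x` (increasing grid) and `mu` (memberships in
#'   `[0, 1]`).
#' @return The crisp diagnosis index (scalar).
#' @export
defuzzify_cog <- function(shape) {
  x <- shape$x
  mu <- shape$mu
  if (length(x) < 2) abort("shape needs at least two grid points")
  dx <- diff(x)
  area <- sum(dx * (mu[-1] + mu[-length(mu)]) / 2)
  if (area <= 0) {
    abort("aggregated shape has zero area: no rule fired, cannot defuzzify")
  }
  xm <- x * mu
  moment <- sum(dx * (xm[-1] + xm[-length(xm)]) / 2)
  moment / area
}

#' Threshold decision on the diagnosis index
#'
#' @param index Crisp diagnosis index (or vector).
#' @param behavior A complex behavior class with a configured threshold.
#' @param engine A [fuzzy_engine()].
#' @return `"Abnormal"` where `index` strictly exceeds the behavior's
#'   threshold, else `"Normal"`.
#' @export
decide <- function(index, behavior, engine = fuzzy_engine()) {
  thr <- unname(engine$thresholds[behavior])
  if (is.na(thr)) abort(paste0("no decision threshold for '", behavior, "'"))
  ifelse(index > thr, "Abnormal", "Normal")
}

#' Full fuzzy diagnosis of a behavior frequency
#'
#' Runs fuzzify, rule inference, center-of-gravity defuzzification and the
#' threshold decision for each supplied frequency.
#'
#' @param f Frequency fraction(s) in `[0, 1]`.
#' @param behavior A complex behavior class.
#' @param engine A [fuzzy_engine()].
#' @return A tibble with columns `behavior`, `f`, `index`, `d`.
#' @export
diagnose <- function(f, behavior, engine = fuzzy_engine()) {
  purrr::map_dfr(as.numeric(f), function(fi) {
    deg <- fuzzify(fi, engine$input)
    shape <- fuzzy_infer(deg, behavior, engine)
    idx <- defuzzify_cog(shape)
    tibble(behavior = behavior, f = fi, index = idx,
           d = decide(idx, behavior, engine))
  })
}

#' Plot the membership functions of a fuzzy engine
#'
#' @param engine A [fuzzy_engine()].
#' @param n Grid points per variable.
#' @return A ggplot object with one panel per linguistic variable.
#' @export
plot_membership <- function(engine = fuzzy_engine(), n = 400) {
  one <- function(v) {
    x <- seq(v$universe[1], v$universe[2], length.out = n)
    purrr::pmap_dfr(v$sets, function(set, a, b, c, d) {
      tibble(variable = v$name, x = x, set = set,
             mu = trapezoid_mu(x, a, b, c, d))
    })
  }
  tbl <- dplyr::bind_rows(one(engine$input), one(engine$output))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$x, .data$mu, colour = .data$set)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "membership", colour = NULL)
}
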