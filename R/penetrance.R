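# Penetrance tables for pure epistatic disease models.
#
# A penetrance table maps each genotype combination of L interacting loci
# (L = 2 or 3, genotypes coded 0/1/2 = copies of the minor allele) to the
# probability of disease given that combination. Tables are built from the
# classical two-locus interaction forms of Marchini-type models (additive,
# multiplicative, threshold) and solved so that the binary trait reaches a
# requested broad-sense heritability on the observed scale.

#' Hardy-Weinberg genotype frequencies for a biallelic locus
#'
#' @param maf Minor-allele frequency, a single value in \code{[0, 0.5]}.
#' @return Numeric vector \code{c(p0, p1, p2)} with the probabilities of
#'   carrying 0, 1 or 2 copies of the minor allele:
#'   \code{(1-q)^2, 2q(1-q), q^2}.
#' @examples
#' hwe_genotype_freqs(0.5)   # c(0.25, 0.5, 0.25)
#' hwe_genotype_freqs(0.25)
#' @export
hwe_genotype_freqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf < 0 || maf > 0.5) {
    stop("`maf` must be a single allele frequency in [0, 0.5], got: ",
         deparse(substitute(maf)), " = ", format(maf), call. = FALSE)
  }
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' An epistasis interaction form
#'
#' Describes one of the three classical two-locus disease models on the
#' penetrance (probability) scale: writing g1, g2 for the minor-allele
#' counts at the interacting loci, the penetrance is
#' \code{baseline * (1 + effect)^e(g)} with exponent
#' \itemize{
#'   \item additive: \code{e = g1 + g2} (effect grows with the total number
#'     of causal alleles, within and between loci);
#'   \item multiplicative: \code{e = g1 * g2} if both loci carry at least
#'     one causal allele, else penetrance stays at \code{baseline};
#'   \item threshold: \code{e = 1} if both loci carry at least one causal
#'     allele, else \code{baseline} (two constant effect levels).
#' }
#' Three-locus tables extend these by summing (additive) or multiplying
#' (multiplicative) all allele counts, and by requiring all loci to carry a
#' causal allele (multiplicative/threshold).
#'
#' @param name One of \code{"additive"}, \code{"multiplicative"},
#'   \code{"threshold"}.
#' @param baseline Baseline penetrance (> 0).
#' @param effect Effect-size parameter (>= 0).
#' @return An object of class \code{"epistasis_form"}.
#' @export
epistasis_form <- function(name, baseline, effect) {
  name <- match.arg(name, c("additive", "multiplicative", "threshold"))
  stopifnot(is.numeric(baseline), length(baseline) == 1L,
            is.numeric(effect), length(effect) == 1L)
  if (!(baseline > 0)) stop("`baseline` must be > 0", call. = FALSE)
  if (!(effect >= 0)) stop("`effect` must be >= 0", call. = FALSE)
  structure(list(name = name, baseline = baseline, effect = effect),
            class = "epistasis_form")
}

#' @export
print.epistasis_form <- function(x, ...) {
  cat(sprintf("<epistasis_form> %s: baseline = %g, effect = %g\n",
              x$name, x$baseline, x$effect))
  invisible(x)
}

# All genotype tuples of `order` loci in lexicographic order (first locus
# most significant): (0,..,0), (0,..,1), ..., (2,..,2).  Row i corresponds
# to linear index i = 1 + sum_l g_l * 3^(order - l).
genotype_tuples <- function(order) {
  g <- as.matrix(rev(expand.grid(rev(lapply(seq_len(order), function(i) 0:2)))))
  dimnames(g) <- list(NULL, paste0("g", seq_len(order)))
  g
}

tuple_labels <- function(tuples) apply(tuples, 1L, paste, collapse = ",")

# Interaction-form multiplier exponents for each genotype tuple.
form_exponent <- function(name, tuples) {
  all_causal <- apply(tuples >= 1L, 1L, all)
  switch(name,
    additive       = rowSums(tuples),
    multiplicative = ifelse(all_causal, apply(tuples, 1L, prod), 0),
    threshold      = ifelse(all_causal, 1, 0))
}

#' Construct a penetrance table
#'
#' Low-level constructor validating the table invariants: one value per
#' genotype tuple in lexicographic order, all values in \code{[0, 1]}.
#'
#' @param order Number of interacting loci (2 or 3).
#' @param mafs Per-locus minor-allele frequencies in \code{(0, 0.5]}
#'   (length \code{order}).
#' @param values Numeric vector of \code{3^order} penetrances in
#'   lexicographic genotype order (first locus most significant).
#' @return An object of class \code{"penetrance_table"} with fields
#'   \code{order}, \code{mafs}, \code{values} (named by genotype tuple)
#'   and \code{tuples}.
#' @export
penetrance_table <- function(order, mafs, values) {
  stopifnot(order %in% c(2L, 3L))
  order <- as.integer(order)
  if (length(mafs) != order) {
    stop("`mafs` must have length ", order, call. = FALSE)
  }
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("all `mafs` must be in (0, 0.5]", call. = FALSE)
  }
  if (length(values) != 3L^order) {
    stop("`values` must have ", 3L^order, " entries for order ", order,
         ", got ", length(values), call. = FALSE)
  }
  bad <- which(values < 0 | values > 1 | is.na(values))
  tuples <- genotype_tuples(order)
  if (length(bad)) {
    stop("penetrance out of [0, 1] at genotype (",
         tuple_labels(tuples)[bad[1L]], "): ", format(values[bad[1L]]),
         call. = FALSE)
  }
  values <- as.numeric(values)
  names(values) <- tuple_labels(tuples)
  structure(list(order = order, mafs = as.numeric(mafs),
                 values = values, tuples = tuples),
            class = "penetrance_table")
}

#' @export
print.penetrance_table <- function(x, ...) {
  cat(sprintf("<penetrance_table> %d loci, MAFs = %s\n", x$order,
              paste(format(x$mafs), collapse = ", ")))
  cat(sprintf("  prevalence = %.6f, heritability = %.6f\n",
              prevalence(x), heritability(x)))
  print(round(x$values, 6))
  invisible(x)
}

# Hardy-Weinberg probability of each genotype tuple (product across loci).
tuple_weights <- function(table) {
  freqs <- lapply(table$mafs, hwe_genotype_freqs)
  w <- rep(1, nrow(table$tuples))
  for (l in seq_len(table$order)) {
    w <- w * freqs[[l]][table$tuples[, l] + 1L]
  }
  w
}

#' Build a Marchini-form penetrance table from explicit parameters
#'
#' Evaluates the interaction form at every genotype combination. Parameter
#' combinations driving any cell above 1 are infeasible and raise an error
#' naming the offending genotype.
#'
#' With \code{effect = 0} every form degenerates to the constant table with
#' all cells equal to \code{baseline}.
#'
#' @param form An \code{\link{epistasis_form}}.
#' @param mafs Per-locus minor-allele frequencies (length 2 or 3).
#' @return A \code{\link{penetrance_table}}; the generating form is kept in
#'   attribute \code{"form"}.
#' @export
marchini_table <- function(form, mafs) {
  stopifnot(inherits(form, "epistasis_form"))
  order <- length(mafs)
  tuples <- genotype_tuples(order)
  expo <- form_exponent(form$name, tuples)
  values <- form$baseline * (1 + form$effect)^expo
  # boundary solutions place the top cell at exactly 1; absorb the few
  # ulps of round-off from the a = (1+e)^-emax construction
  values[values > 1 & values <= 1 + 1e-9] <- 1
  over <- which(values > 1)
  if (length(over)) {
    i <- over[which.max(values[over])]
    stop(sprintf(
      "infeasible %s form (baseline = %g, effect = %g): penetrance %.6g > 1 at genotype (%s)",
      form$name, form$baseline, form$effect, values[i],
      tuple_labels(tuples)[i]), call. = FALSE)
  }
  tab <- penetrance_table(order, mafs, values)
  attr(tab, "form") <- form
  tab
}

#' Population prevalence of a penetrance table
#'
#' Marginal disease probability \code{sum_g P(g) p_g}, with \code{P(g)} the
#' Hardy-Weinberg product of per-locus genotype frequencies.
#'
#' @param table A \code{\link{penetrance_table}}.
#' @return Prevalence in \code{[0, 1]}.
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  sum(tuple_weights(table) * table$values)
}

#' Broad-sense heritability of a penetrance table on the observed scale
#'
#' \code{sum_g P(g) (p_g - pi)^2 / (pi (1 - pi))} with \code{pi} the
#' prevalence: the proportion of variance of the 0/1 trait explained by
#' genotype. This is the observed-scale (not liability-scale) definition
#' used by the GAMETES family of simulators.
#'
#' @param table A \code{\link{penetrance_table}}.
#' @return Heritability in \code{[0, 1]}.
#' @export
heritability <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  w <- tuple_weights(table)
  pi <- sum(w * table$values)
  if (pi <= 0 || pi >= 1) {
    stop("heritability undefined: prevalence is ", format(pi), call. = FALSE)
  }
  sum(w * (table$values - pi)^2) / (pi * (1 - pi))
}

# Heritability of the table a(t) * multiplier(t) where the baseline a is on
# the feasibility boundary a = 1/max(multiplier). Used by the solver.
boundary_h2 <- function(name, log_effect, mafs, weights, tuples) {
  m <- (1 + exp(log_effect))^form_exponent(name, tuples)
  p <- m / max(m)
  pi <- sum(weights * p)
  sum(weights * (p - pi)^2) / (pi * (1 - pi))
}

#' Solve a penetrance table for a target heritability
#'
#' Finds Marchini-form parameters \code{(baseline, effect)} whose table
#' attains the requested broad-sense heritability. The single heritability
#' constraint leaves a one-parameter family of solutions; following the
#' Toxo/PyTOXO convention, the solver returns the member maximizing
#' prevalence subject to all penetrances <= 1. Along the heritability
#' contour prevalence is maximal at the smallest feasible effect, where the
#' largest penetrance cell equals exactly 1, so the problem reduces to a
#' bracketed 1-D root-find on \code{log(effect)} with
#' \code{baseline = (1 + effect)^-e_max}.
#'
#' @param form_name \code{"additive"}, \code{"multiplicative"} or
#'   \code{"threshold"}.
#' @param mafs Per-locus minor-allele frequencies (length 2 or 3).
#' @param target_h2 Target heritability in \code{(0, 1)}.
#' @param tol Convergence tolerance on the achieved heritability
#'   (default \code{1e-10}; the contract guarantees \code{1e-6}).
#' @return A \code{\link{penetrance_table}} whose \code{\link{heritability}}
#'   equals \code{target_h2} to within \code{tol}; the solved
#'   \code{\link{epistasis_form}} is kept in attribute \code{"form"}.
#' @examples
#' tab <- solve_penetrance("threshold", c(0.25, 0.25), 0.25)
#' heritability(tab)  # 0.25
#' prevalence(tab)
#' @export
solve_penetrance <- function(form_name, mafs, target_h2, tol = 1e-10) {
  form_name <- match.arg(form_name,
                         c("additive", "multiplicative", "threshold"))
  if (!is.numeric(target_h2) || length(target_h2) != 1L ||
      target_h2 <= 0 || target_h2 >= 1) {
    stop("`target_h2` must be in (0, 1)", call. = FALSE)
  }
  order <- length(mafs)
  tuples <- genotype_tuples(order)
  w <- {
    tmp <- penetrance_table(order, mafs, rep(0.5, 3^order))
    tuple_weights(tmp)
  }
  h2_of <- function(le) boundary_h2(form_name, le, mafs, w, tuples)

  # Boundary heritability rises from 0 (effect -> 0); locate a bracket, or
  # report infeasibility with the maximum achievable value.
  grid <- seq(log(1e-9), log(1e9), length.out = 400L)
  hs <- vapply(grid, h2_of, numeric(1))
  imax <- which.max(hs)
  if (hs[imax] < target_h2) {
    stop(sprintf(
      "no feasible %s table at MAFs (%s) reaches heritability %g; maximum achievable is %.6g",
      form_name, paste(format(mafs), collapse = ", "), target_h2, hs[imax]),
      call. = FALSE)
  }
  hi <- grid[which(hs >= target_h2)[1L]]
  lo <- if (which(hs >= target_h2)[1L] > 1L) grid[which(hs >= target_h2)[1L] - 1L] else log(1e-12)
  root <- stats::uniroot(function(le) h2_of(le) - target_h2,
                         c(lo, hi), tol = .Machine$double.eps^0.75)$root
  effect <- exp(root)
  baseline <- (1 + effect)^(-max(form_exponent(form_name, tuples)))
  tab <- marchini_table(epistasis_form(form_name, baseline, effect), mafs)
  achieved <- heritability(tab)
  if (abs(achieved - target_h2) > max(tol, 1e-6)) {
    stop(sprintf("solver failed to converge: achieved h2 = %.10g, target %g",
                 achieved, target_h2), call. = FALSE)
  }
  tab
}

#' Write a penetrance table to a plain-text file
#'
#' Format: header lines \code{#order=<L>} and \code{#maf=<q1,q2[,q3]>},
#' then \code{3^L} lines \code{g1,g2[,g3]<TAB>penetrance} in lexicographic
#' genotype order, penetrances at 12 significant digits.
#'
#' @param table A \code{\link{penetrance_table}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_penetrance_table <- function(table, path) {
  stopifnot(inherits(table, "penetrance_table"))
  lines <- c(
    paste0("#order=", table$order),
    paste0("#maf=", paste(format(table$mafs, digits = 12), collapse = ",")),
    paste0(tuple_labels(table$tuples), "\t",
           formatC(table$values, digits = 12, format = "g"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a penetrance table written by \code{\link{write_penetrance_table}}
#'
#' @param path File path.
#' @return A \code{\link{penetrance_table}}.
#' @export
read_penetrance_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#order=") ||
      !startsWith(lines[2L], "#maf=")) {
    stop("malformed penetrance table file (expected '#order=' and '#maf=' headers): ",
         path, call. = FALSE)
  }
  order <- suppressWarnings(as.integer(sub("^#order=", "", lines[1L])))
  if (is.na(order) || !order %in% c(2L, 3L)) {
    stop("line 1: invalid order in ", path, call. = FALSE)
  }
  mafs <- suppressWarnings(as.numeric(strsplit(sub("^#maf=", "", lines[2L]), ",")[[1L]]))
  if (anyNA(mafs) || length(mafs) != order) {
    stop("line 2: expected ", order, " comma-separated MAFs", call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 3L^order) {
    stop(sprintf("expected %d genotype lines for order %d, found %d",
                 3L^order, order, length(body)), call. = FALSE)
  }
  expected <- tuple_labels(genotype_tuples(order))
  values <- numeric(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    lineno <- i + 2L
    if (length(parts) != 2L) {
      stop("line ", lineno, ": expected '<genotype>\\t<penetrance>'",
           call. = FALSE)
    }
    if (parts[1L] != expected[i]) {
      stop("line ", lineno, ": genotype tuple out of order, expected (",
           expected[i], ") got (", parts[1L], ")", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(v)) stop("line ", lineno, ": non-numeric penetrance", call. = FALSE)
    if (v < 0 || v > 1) {
      stop("line ", lineno, ": penetrance ", format(v), " outside [0, 1]",
           call. = FALSE)
    }
    values[i] <- v
  }
  penetrance_table(order, mafs, values)
}
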