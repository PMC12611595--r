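# Constraint-function templates over dose rings for two TPS dialects
# (Monaco VMAT single-target / SIB, Pinnacle IMRT), plus a documented
# quadratic-hinge penalty evaluator. The template *content* (cost types,
# weights, reference doses, isoconstraints) is fixed; the penalty algebra is
# this package's own stand-in for the proprietary TPS cost formulas.

COST_TYPES <- c("target_penalty", "underdose_dvh", "overdose_dvh",
                "maximum_dose", "minimum_dose", "min_dvh", "uniform_dose")

ring_name <- function(k) sprintf("Ring %d", k)

#' Name of a ring/organ intersection structure
#' @param k ring level (integer Gy).
#' @param organ organ name.
#' @return The conventional structure name `"Ring k \u2229 organ"`.
#' @export
ring_organ_name <- function(k, organ) sprintf("Ring %d \u2229 %s", k, organ)

cf_row <- function(structure, cost, weight, ref_cgy = NA_real_, iso = NA_real_) {
  data.frame(structure = structure, cost = cost, weight = weight,
             ref_cgy = ref_cgy, iso = iso, stringsAsFactors = FALSE)
}

#' Build a dose-ring constraint template
#'
#' Generates the ordered constraint functions of one planning dialect:
#'
#' * `monaco_vmat_single` (n = 45): Ring 45 target penalty (weight 10,
#'   isoconstraint 4500 cGy); Ring 44 down to Ring `min_level` overdose DVH
#'   (weight 0.01, reference dose `(k+1)*100` cGy, isoconstraint 0.01%);
#'   Body maximum dose (weight 1, 5000 cGy).
#' * `monaco_vmat_sib` (n = 50): Ring 50 target penalty (1.00 / 5000),
#'   underdose DVH (100.00 / 5000 cGy / 96.50%), maximum dose (10.00 /
#'   5500); Ring 45 target penalty (3.00 / 4500), underdose DVH (100.00 /
#'   4500 / 98.50%), maximum dose (1.00 / 5000); the same overdose-DVH ring
#'   chain; Body maximum dose (1.00 / 5500).
#' * `pinnacle_imrt` (n = 45): Ring 45 minimum dose (100.00 / 4500 cGy),
#'   maximum dose (80.00 / 4650), min DVH (100.00 / 4500 at 100%), uniform
#'   dose (10.00 / 4550); Ring 44..`min_level` maximum dose (0.01 /
#'   `(k+1)*100`); and for each organ the intersections Ring \{30, 33, 36,
#'   39\} x organ with maximum dose (0.01 / `k*100`).
#'
#' Constraints are never attached to rings below `min_level` (low-dose rings
#' are excluded for planning efficiency).
#'
#' @param dialect one of `"monaco_vmat_single"`, `"monaco_vmat_sib"`,
#'   `"pinnacle_imrt"`.
#' @param n prescription-level ring count (integer Gy); defaults to 50 for
#'   the SIB dialect, 45 otherwise.
#' @param min_level lowest constrained ring (default 25).
#' @param organs organ names for the IMRT intersection constraints; the
#'   default placeholder `"organ"` yields the generic rows.
#' @return An object of class `constraint_template` with fields `dialect`,
#'   `n`, `min_level`, `organs` and `functions` (a data.frame with columns
#'   `structure`, `cost`, `weight`, `ref_cgy`, `iso`).
#' @export
build_template <- function(dialect = c("monaco_vmat_single", "monaco_vmat_sib",
                                       "pinnacle_imrt"),
                           n = NULL, min_level = 25, organs = "organ") {
  dialect <- match.arg(dialect)
  if (is.null(n)) n <- if (dialect == "monaco_vmat_sib") 50L else 45L
  n <- as.integer(n)
  if (n < min_level) stop("build_template: n must be >= min_level")
  overdose_chain <- function(cost, weight) {
    ks <- seq(n_base(dialect, n) - 1, min_level)
    do.call(rbind, lapply(ks, function(k) {
      cf_row(ring_name(k), cost, weight, ref_cgy = (k + 1) * 100,
             iso = if (cost == "overdose_dvh") 0.01 else NA_real_)
    }))
  }
  funs <- switch(dialect,
    monaco_vmat_single = rbind(
      cf_row(ring_name(n), "target_penalty", 10, iso = n * 100),
      overdose_chain("overdose_dvh", 0.01),
      cf_row("Body", "maximum_dose", 1, iso = (n + 5) * 100)),
    monaco_vmat_sib = {
      nb <- n - 5  # base prescription level under the boost
      rbind(
        cf_row(ring_name(n), "target_penalty", 1.00, iso = n * 100),
        cf_row(ring_name(n), "underdose_dvh", 100.00, ref_cgy = n * 100, iso = 96.50),
        cf_row(ring_name(n), "maximum_dose", 10.00, iso = (n + 5) * 100),
        cf_row(ring_name(nb), "target_penalty", 3.00, iso = nb * 100),
        cf_row(ring_name(nb), "underdose_dvh", 100.00, ref_cgy = nb * 100, iso = 98.50),
        cf_row(ring_name(nb), "maximum_dose", 1.00, iso = (nb + 5) * 100),
        overdose_chain("overdose_dvh", 0.01),
        cf_row("Body", "maximum_dose", 1.00, iso = (n + 5) * 100))
    },
    pinnacle_imrt = {
      inter <- do.call(rbind, lapply(organs, function(org) {
        do.call(rbind, lapply(c(30, 33, 36, 39), function(k) {
          cf_row(ring_organ_name(k, org), "maximum_dose", 0.01, ref_cgy = k * 100)
        }))
      }))
      rbind(
        cf_row(ring_name(n), "minimum_dose", 100.00, ref_cgy = n * 100),
        cf_row(ring_name(n), "maximum_dose", 80.00, ref_cgy = n * 100 + 150),
        cf_row(ring_name(n), "min_dvh", 100.00, ref_cgy = n * 100, iso = 100),
        cf_row(ring_name(n), "uniform_dose", 10.00, ref_cgy = n * 100 + 50),
        overdose_chain("maximum_dose", 0.01),
        inter)
    })
  rownames(funs) <- NULL
  structure(list(dialect = dialect, n = n, min_level = as.integer(min_level),
                 organs = organs, functions = funs),
            class = "constraint_template")
}

# For the SIB dialect the overdose chain starts below the 45 Gy base target,
# not below the 50 Gy boost.
n_base <- function(dialect, n) if (dialect == "monaco_vmat_sib") n - 5 else n

#' @export
print.constraint_template <- function(x, ...) {
  cat(sprintf("<constraint_template> %s, n = %d, rings >= %d, %d functions\n",
              x$dialect, x$n, x$min_level, nrow(x$functions)))
  invisible(x)
}

#' Look up constraint functions of a template
#'
#' @param template a `constraint_template`.
#' @param structure structure name (e.g. `"Ring 43"`).
#' @param cost optional cost type filter.
#' @return The matching rows of `template$functions`.
#' @export
template_functions <- function(template, structure = NULL, cost = NULL) {
  f <- template$functions
  if (!is.null(structure)) f <- f[f$structure == structure, , drop = FALSE]
  if (!is.null(cost)) f <- f[f$cost == cost, , drop = FALSE]
  f
}

#' Serialize a constraint template to tabular text
#'
#' Human-readable, lossless tab-separated format: a `#` header with dialect,
#' `n`, minimum ring level and organs, then one line per constraint
#' function (`structure  cost  weight  reference_dose_cGy  isoconstraint`,
#' empty fields written as `-`).
#'
#' @param template a `constraint_template`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
serialize_template <- function(template, path) {
  stopifnot(inherits(template, "constraint_template"))
  if (nrow(template$functions) == 0) stop("serialize_template: empty template")
  fmt <- function(x) ifelse(is.na(x), "-", sub("\\.?0+$", "", sprintf("%.2f", x)))
  f <- template$functions
  lines <- c(
    sprintf("# dialect: %s", template$dialect),
    sprintf("# n: %d", template$n),
    sprintf("# min_level: %d", template$min_level),
    sprintf("# organs: %s", paste(template$organs, collapse = ",")),
    paste("structure", "cost", "weight", "reference_dose_cGy", "isoconstraint",
          sep = "\t"),
    sprintf("%s\t%s\t%s\t%s\t%s", f$structure, f$cost, fmt(f$weight),
            fmt(f$ref_cgy), fmt(f$iso)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Parse a serialized constraint template
#'
#' Exact inverse of [serialize_template()].
#'
#' @param path file path.
#' @return A `constraint_template`.
#' @export
parse_template <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  header <- function(key, lineno) {
    pat <- sprintf("^# %s: (.*)$", key)
    if (lineno > length(lines) || !grepl(pat, lines[lineno])) {
      stop(sprintf("parse_template: line %d: expected '# %s: ...'", lineno, key))
    }
    sub(pat, "\\1", lines[lineno])
  }
  dialect <- header("dialect", 1)
  n <- as.integer(header("n", 2))
  min_level <- as.integer(header("min_level", 3))
  organs <- strsplit(header("organs", 4), ",")[[1]]
  if (length(lines) < 6) stop("parse_template: line 6: no constraint rows")
  num <- function(s, lineno) {
    ifelse(s == "-", NA_real_, suppressWarnings(as.numeric(s)))
  }
  rows <- lapply(seq(6, length(lines)), function(i) {
    if (lines[i] == "") return(NULL)
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 5) {
      stop(sprintf("parse_template: line %d: expected 5 tab-separated fields", i))
    }
    if (!parts[2] %in% COST_TYPES) {
      stop(sprintf("parse_template: line %d: unknown cost type '%s'", i, parts[2]))
    }
    w <- num(parts[3], i)
    if (is.na(w)) stop(sprintf("parse_template: line %d: weight is required", i))
    cf_row(parts[1], parts[2], w, num(parts[4], i), num(parts[5], i))
  })
  funs <- do.call(rbind, rows)
  structure(list(dialect = dialect, n = n, min_level = min_level,
                 organs = organs, functions = funs),
            class = "constraint_template")
}

#' Evaluate the penalty objective of a template against a dose grid
#'
#' Quadratic-hinge penalty per constraint function (all in Gy / percent
#' units; reference doses converted from cGy):
#' * `maximum_dose`: mean over the structure of `max(0, d - ref)^2`
#' * `minimum_dose`: mean of `max(0, ref - d)^2`
#' * `uniform_dose`: mean of `(d - ref)^2`
#' * `overdose_dvh`: `max(0, V_ref% - isoconstraint)^2`
#' * `underdose_dvh`, `min_dvh`: `max(0, isoconstraint - V_ref%)^2`
#' * `target_penalty`: `max(0, 95 - V_iso%)^2` (95% coverage rule)
#'
#' Monaco-style rows carry the dose bound in the isoconstraint column; for
#' the dose-type costs the effective bound is `ref_cgy` when present, else
#' `iso`. The total is the weight-linear sum of penalties.
#'
#' @param dose a [dose_grid()].
#' @param template a `constraint_template`.
#' @param structures a [structure_set()] resolving every structure the
#'   template references (rings, intersections, Body, ...).
#' @return `list(per_function = <data.frame with penalty and contribution
#'   columns>, total = <weighted sum>)`.
#' @export
evaluate_objective <- function(dose, template, structures) {
  stopifnot(inherits(dose, "dose_grid"), inherits(template, "constraint_template"),
            inherits(structures, "structure_set"))
  f <- template$functions
  missing_names <- setdiff(unique(f$structure), names(structures))
  if (length(missing_names) > 0) {
    stop(sprintf("evaluate_objective: unresolved structures: %s",
                 paste(missing_names, collapse = ", ")))
  }
  penalty <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    mask <- structures[[f$structure[i]]]
    if (sum(mask$values) == 0) { penalty[i] <- 0; next }
    d <- dose$values[mask$values > 0.5]
    bound_gy <- (if (!is.na(f$ref_cgy[i])) f$ref_cgy[i] else f$iso[i]) / 100
    penalty[i] <- switch(f$cost[i],
      maximum_dose = mean(pmax(0, d - bound_gy)^2),
      minimum_dose = mean(pmax(0, bound_gy - d)^2),
      uniform_dose = mean((d - bound_gy)^2),
      overdose_dvh = max(0, 100 * mean(d >= f$ref_cgy[i] / 100) - f$iso[i])^2,
      underdose_dvh = max(0, f$iso[i] - 100 * mean(d >= f$ref_cgy[i] / 100))^2,
      min_dvh = max(0, f$iso[i] - 100 * mean(d >= f$ref_cgy[i] / 100))^2,
      target_penalty = max(0, 95 - 100 * mean(d >= f$iso[i] / 100))^2,
      stop(sprintf("unknown cost type '%s'", f$cost[i])))
  }
  per <- cbind(f, penalty = penalty, contribution = f$weight * penalty)
  list(per_function = per, total = sum(per$contribution))
}
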