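#' Construct a RuleSet
#'
#' @param classes character vector of class labels, one per rule.
#' @param ndvi_min,ndvi_max,bbst_min,bbst_max numeric bounds per class;
#'   use \code{-Inf}/\code{Inf} for one-sided conditions. BBST bounds are
#'   in Celsius.
#' @param ndvi_min_incl,ndvi_max_incl,bbst_min_incl,bbst_max_incl logical,
#'   whether each finite bound is inclusive.
#' @param precedence class order for first-match assignment; defaults to
#'   the order of \code{classes}.
#' @return A \linkS4class{RuleSet}.
#' @export
ruleSet <- function(classes, ndvi_min, ndvi_max, bbst_min, bbst_max,
                    ndvi_min_incl = TRUE, ndvi_max_incl = TRUE,
                    bbst_min_incl = TRUE, bbst_max_incl = TRUE,
                    precedence = classes) {
  n <- length(classes)
  r <- data.frame(class = as.character(classes),
                  ndvi_min = rep_len(ndvi_min, n),
                  ndvi_max = rep_len(ndvi_max, n),
                  ndvi_min_incl = rep_len(ndvi_min_incl, n),
                  ndvi_max_incl = rep_len(ndvi_max_incl, n),
                  bbst_min = rep_len(bbst_min, n),
                  bbst_max = rep_len(bbst_max, n),
                  bbst_min_incl = rep_len(bbst_min_incl, n),
                  bbst_max_incl = rep_len(bbst_max_incl, n),
                  stringsAsFactors = FALSE)
  new("RuleSet", rules = r, precedence = as.character(precedence))
}

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet (precedence: ", paste(object@precedence, collapse = " > "),
      ")\n", sep = "")
  r <- object@rules
  fmt <- function(lo, hi, li, hi_i) {
    l <- if (is.finite(lo)) sprintf("%s%g", if (li) ">= " else "> ", lo) else NULL
    h <- if (is.finite(hi)) sprintf("%s%g", if (hi_i) "<= " else "< ", hi) else NULL
    paste(c(l, h), collapse = " and ")
  }
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-10s NDVI %s;  BBST %s degC\n", r$class[i],
                fmt(r$ndvi_min[i], r$ndvi_max[i], r$ndvi_min_incl[i],
                    r$ndvi_max_incl[i]),
                fmt(r$bbst_min[i], r$bbst_max[i], r$bbst_min_incl[i],
                    r$bbst_max_incl[i])))
  invisible(NULL)
})

#' Read or write a RuleSet as a JSON config
#'
#' The serialization keeps thresholds, bound inclusivity and precedence
#' bit-exact so a published rule set is a reproducible input.
#'
#' @param path file path.
#' @return \code{readRuleSet} returns a \linkS4class{RuleSet};
#'   \code{writeRuleSet} returns \code{path} invisibly.
#' @export
readRuleSet <- function(path) {
  cfg <- jsonlite::read_json(path)
  classes <- names(cfg$rules)
  get <- function(cl, cov, field, default)
    if (!is.null(cfg$rules[[cl]][[cov]][[field]]))
      cfg$rules[[cl]][[cov]][[field]] else default
  num <- function(cov, field, default)
    vapply(classes, get, numeric(1), cov = cov, field = field,
           default = default)
  lgl <- function(cov, field)
    vapply(classes, get, logical(1), cov = cov, field = field, default = TRUE)
  ruleSet(classes,
          ndvi_min = num("ndvi", "min", -Inf),
          ndvi_max = num("ndvi", "max", Inf),
          bbst_min = num("bbst", "min", -Inf),
          bbst_max = num("bbst", "max", Inf),
          ndvi_min_incl = lgl("ndvi", "min_inclusive"),
          ndvi_max_incl = lgl("ndvi", "max_inclusive"),
          bbst_min_incl = lgl("bbst", "min_inclusive"),
          bbst_max_incl = lgl("bbst", "max_inclusive"),
          precedence = unlist(cfg$precedence))
}

#' @rdname readRuleSet
#' @param rules a \linkS4class{RuleSet} to serialize.
#' @export
writeRuleSet <- function(rules, path) {
  r <- rules@rules
  cov <- function(i, pre) {
    out <- list()
    lo <- r[[paste0(pre, "_min")]][i]; hi <- r[[paste0(pre, "_max")]][i]
    if (is.finite(lo)) {
      out$min <- lo; out$min_inclusive <- r[[paste0(pre, "_min_incl")]][i]
    }
    if (is.finite(hi)) {
      out$max <- hi; out$max_inclusive <- r[[paste0(pre, "_max_incl")]][i]
    }
    out
  }
  rl <- lapply(seq_len(nrow(r)), function(i)
    list(ndvi = cov(i, "ndvi"), bbst = cov(i, "bbst")))
  names(rl) <- r$class
  jsonlite::write_json(list(precedence = rules@precedence, rules = rl),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The published wet-season reference rule set
#'
#' The coupled NDVI x BBST thresholds derived from wet-season field
#' training data over a southern-African savanna: woodland has NDVI above
#' 0.41 with BBST below 36.5 degC, grassland NDVI below 0.36 with BBST
#' above 38.6 degC, and shrubland sits in the inclusive box NDVI 0.28-0.51
#' by BBST 36.7-39.3 degC. Classes are tested woodland, then grassland,
#' then shrubland. Loaded from the JSON config shipped with the package so
#' the published thresholds are bit-exact inputs, not code constants.
#'
#' @return A \linkS4class{RuleSet}.
#' @export
#' @examples
#' referenceRuleSet()
referenceRuleSet <- function() {
  readRuleSet(system.file("extdata", "wet_season_rules.json",
                          package = "savannacover", mustWork = TRUE))
}

## Per-class condition test on ndvi/bbst vectors; NA-safe (NA -> FALSE).
.ruleMatch <- function(rule, ndvi, bbst) {
  cmp <- function(x, lo, hi, li, hi_i) {
    ok <- rep(TRUE, length(x))
    if (is.finite(lo)) ok <- ok & (if (li) x >= lo else x > lo)
    if (is.finite(hi)) ok <- ok & (if (hi_i) x <= hi else x < hi)
    ok
  }
  ok <- cmp(ndvi, rule$ndvi_min, rule$ndvi_max, rule$ndvi_min_incl,
            rule$ndvi_max_incl) &
    cmp(bbst, rule$bbst_min, rule$bbst_max, rule$bbst_min_incl,
        rule$bbst_max_incl)
  ok & !is.na(ok)
}

#' Test which samples satisfy a given class's rule conditions
#'
#' @param rules a \linkS4class{RuleSet}.
#' @param class class label whose conditions to test.
#' @param ndvi,bbst numeric vectors (BBST in Celsius).
#' @return Logical vector, TRUE where both conditions hold.
#' @export
ruleMatches <- function(rules, class, ndvi, bbst) {
  i <- match(class, rules@rules$class)
  if (is.na(i)) stop("no rule for class '", class, "'")
  .ruleMatch(rules@rules[i, ], ndvi, bbst)
}

#' Induce box rules from training samples by empirical quantiles
#'
#' A reproducible surrogate for manually reading class boundaries off the
#' NDVI-versus-BBST scatter: each class's NDVI and BBST conditions are the
#' closed empirical quantile intervals \code{[lowerQ, upperQ]} of that
#' class's training pixels. The default [0.02, 0.98] trims 2% tails so a
#' few outlying pixels cannot inflate a class box.
#'
#' @param samples a pixel sample table as returned by
#'   \code{\link{extractPixels}} (columns class, ndvi, bbst).
#' @param lowerQ,upperQ quantile levels, 0 <= lowerQ < upperQ <= 1.
#' @param precedence class order for first-match assignment.
#' @return A \linkS4class{RuleSet} with inclusive interval conditions.
#' @export
induceRules <- function(samples, lowerQ = 0.02, upperQ = 0.98,
                        precedence = c("woodland", "grassland", "shrubland")) {
  stopifnot(lowerQ >= 0, upperQ <= 1, lowerQ < upperQ)
  classes <- precedence
  counts <- table(factor(samples$class, levels = classes))
  if (any(counts < 10L))
    stop("induction needs >= 10 samples per class; too few for: ",
         paste(names(counts)[counts < 10L], collapse = ", "))
  q <- function(v, cl) stats::quantile(samples[[v]][samples$class == cl],
                                       c(lowerQ, upperQ), names = FALSE)
  nq <- vapply(classes, q, numeric(2), v = "ndvi")
  bq <- vapply(classes, q, numeric(2), v = "bbst")
  ruleSet(classes, ndvi_min = nq[1, ], ndvi_max = nq[2, ],
          bbst_min = bq[1, ], bbst_max = bq[2, ], precedence = precedence)
}

#' Classify a scene with a rule set
#'
#' Pixels are tested class by class in precedence order; the first class
#' whose NDVI and BBST conditions both hold is assigned. Pixels matching
#' no rule are coded 0 (unclassified); nodata in either input propagates
#' to nodata output.
#'
#' @param ndvi an \linkS4class{NdviGrid}.
#' @param bbst a \linkS4class{TemperatureGrid} in Celsius.
#' @param rules a \linkS4class{RuleSet}.
#' @return A \linkS4class{ClassGrid}.
#' @export
#' @examples
#' nd <- rasterGrid(matrix(c(0.55, 0.30, 0.39), 1), class = "NdviGrid")
#' bt <- rasterGrid(matrix(c(34, 39, 36.6), 1), class = "TemperatureGrid",
#'                  unit = "celsius")
#' gridValues(applyRules(nd, bt, referenceRuleSet()))  # 3, 1, 0
applyRules <- function(ndvi, bbst, rules) {
  stopifnot(is(rules, "RuleSet"))
  validObject(rules)
  checkCoregistered(ndvi, bbst)
  if (is(bbst, "TemperatureGrid") && bbst@unit != "celsius")
    bbst <- convertTemperature(bbst, "celsius")
  v <- ndvi@values; t <- bbst@values
  out <- matrix(0L, nrow(v), ncol(v))
  legend <- classLegend()
  assigned <- matrix(FALSE, nrow(v), ncol(v))
  for (cl in rules@precedence) {
    i <- match(cl, rules@rules$class)
    hit <- .ruleMatch(rules@rules[i, ], v, t) & !assigned
    out[hit] <- legend[[cl]]
    assigned <- assigned | hit
  }
  out[is.na(v) | is.na(t)] <- NA_integer_
  rasterGrid(out, ndvi@xll, ndvi@yll, ndvi@cellsize, class = "ClassGrid")
}

#' Per-class area fractions of a class map
#'
#' @param map a \linkS4class{ClassGrid}.
#' @param includeUnclassified if TRUE, percentages are over all unmasked
#'   pixels including unclassified ones; if FALSE (default) unclassified
#'   pixels are dropped and percentages renormalize over the three cover
#'   classes.
#' @return Named numeric vector of percentages summing to 100 (tol 1e-9)
#'   over the included legend.
#' @export
classProportions <- function(map, includeUnclassified = FALSE) {
  v <- map@values[!is.na(map@values)]
  if (!length(v)) stop("class map has no unmasked pixels")
  if (!includeUnclassified) {
    v <- v[v != 0L]
    if (!length(v)) stop("class map has no classified pixels")
    levels <- classLegend()[coverClasses()]
  } else {
    levels <- classLegend()
  }
  counts <- vapply(levels, function(code) sum(v == code), numeric(1))
  100 * counts / sum(counts)
}

#' Own-rule recall of a rule set on a sample table
#'
#' For each class, the fraction of that class's samples satisfying its own
#' rule conditions (box membership, before any precedence-based
#' assignment). For quantile-induced rules evaluated on the inducing
#' samples this is bounded below by 1 minus the four trimmed tails.
#'
#' @param samples pixel sample table (columns class, ndvi, bbst).
#' @param rules a \linkS4class{RuleSet}.
#' @return Named numeric vector of per-class recall fractions in [0, 1].
#' @export
ruleRecall <- function(samples, rules) {
  classes <- intersect(rules@rules$class, unique(samples$class))
  vapply(classes, function(cl) {
    sel <- samples$class == cl
    mean(ruleMatches(rules, cl, samples$ndvi[sel], samples$bbst[sel]))
  }, numeric(1))
}
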