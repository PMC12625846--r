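# Trait harmonization: unit conversions, brain-data QC, BMR averaging,
# residualization and model-frame preparation.

#' Conversion specifications
#'
#' A conversion spec captures one of the unit conversions used to put
#' heterogeneous newborn-size measurements on a common gram scale:
#' `length_weight` (mass = a * length^b, the standard fish length-weight
#' relation), `egg_sphere` (sphere volume at a given density),
#' `egg_to_hatchling` (log10-linear regression of hatchling mass on egg
#' mass), and `identity` (pass-through, used for turtle/crocodile egg
#' masses, which are not converted).
#'
#' @param kind One of `"length_weight"`, `"egg_sphere"`,
#'   `"egg_to_hatchling"`, `"identity"`.
#' @param a,b Coefficients: for `length_weight`, mass = a * L^b (a > 0);
#'   for `egg_to_hatchling`, slope `a` and intercept `b` on the log10
#'   scale.
#' @param density_g_cm3 Density for `egg_sphere` (default 1).
#' @return A list of class `conversion_spec`.
#' @export
conversion_spec <- function(kind = c("length_weight", "egg_sphere",
                                     "egg_to_hatchling", "identity"),
                            a = NA_real_, b = NA_real_, density_g_cm3 = 1) {
  kind <- match.arg(kind)
  if (kind == "length_weight" && (!is.finite(a) || a <= 0)) {
    stop("length_weight conversion requires a > 0")
  }
  if (kind == "egg_to_hatchling" && (!is.finite(a) || !is.finite(b))) {
    stop("egg_to_hatchling conversion requires slope a and intercept b")
  }
  if (!is.finite(density_g_cm3) || density_g_cm3 <= 0) {
    stop("density must be positive")
  }
  structure(list(kind = kind, a = a, b = b, density_g_cm3 = density_g_cm3),
            class = "conversion_spec")
}

#' Convert body length to body mass
#'
#' Applies the allometric length-weight relation mass = a * length^b.
#'
#' @param length_cm Positive length(s) in cm.
#' @param spec A `conversion_spec` of kind `length_weight`.
#' @return Mass in grams.
#' @export
length_to_mass <- function(length_cm, spec) {
  stopifnot(inherits(spec, "conversion_spec"), spec$kind == "length_weight")
  if (any(!is.finite(length_cm)) || any(length_cm <= 0)) {
    stop("lengths must be positive")
  }
  spec$a * length_cm^spec$b
}

#' Convert egg diameter to egg mass
#'
#' Treats the egg as a sphere: mass = density * (pi/6) * d^3, with density
#' 1 g/cm^3 by default.
#'
#' @param diameter_cm Positive diameter(s) in cm.
#' @param density_g_cm3 Density in g/cm^3.
#' @return Mass in grams.
#' @export
egg_diameter_to_mass <- function(diameter_cm, density_g_cm3 = 1) {
  if (any(!is.finite(diameter_cm)) || any(diameter_cm <= 0)) {
    stop("diameters must be positive")
  }
  if (!is.finite(density_g_cm3) || density_g_cm3 <= 0) {
    stop("density must be positive")
  }
  density_g_cm3 * (pi / 6) * diameter_cm^3
}

#' Convert egg mass to hatchling mass
#'
#' Applies a log10-linear egg-to-hatchling regression:
#' hatchling = 10^(slope * log10(egg) + intercept). The coefficients used
#' for birds (fit on n = 453 species) are slope 0.936, intercept -0.158.
#'
#' @param egg_mass_g Positive egg mass(es) in grams.
#' @param spec A `conversion_spec` of kind `egg_to_hatchling` (slope in
#'   `a`, intercept in `b`), or of kind `identity` for a pass-through.
#' @return Hatchling mass in grams.
#' @export
egg_to_hatchling_mass <- function(egg_mass_g, spec) {
  stopifnot(inherits(spec, "conversion_spec"))
  if (any(!is.finite(egg_mass_g)) || any(egg_mass_g <= 0)) {
    stop("egg masses must be positive")
  }
  if (spec$kind == "identity") return(egg_mass_g)
  stopifnot(spec$kind == "egg_to_hatchling")
  10^(spec$a * log10(egg_mass_g) + spec$b)
}

#' Fit an egg-to-hatchling conversion regression
#'
#' Ordinary least squares of log10(hatchling mass) on log10(egg mass).
#'
#' @param egg_mass_g,hatchling_mass_g Paired positive masses (>= 3 pairs).
#' @return A `conversion_spec` of kind `egg_to_hatchling` with extra fields
#'   `n` and `r_squared`.
#' @export
fit_conversion_regression <- function(egg_mass_g, hatchling_mass_g) {
  if (length(egg_mass_g) != length(hatchling_mass_g)) {
    stop("egg and hatchling vectors must have equal length")
  }
  if (length(egg_mass_g) < 3) stop("need at least 3 pairs")
  if (any(egg_mass_g <= 0) || any(hatchling_mass_g <= 0)) {
    stop("masses must be positive")
  }
  lx <- log10(egg_mass_g); ly <- log10(hatchling_mass_g)
  if (var(lx) == 0) stop("zero variance in egg mass: slope undefined")
  fit <- lm(ly ~ lx)
  out <- conversion_spec("egg_to_hatchling",
                         a = unname(coef(fit)[2]), b = unname(coef(fit)[1]))
  out$n <- length(lx)
  out$r_squared <- 1 - sum(resid(fit)^2) / sum((ly - mean(ly))^2)
  out
}

# ---- Brain-data quality control --------------------------------------------

#' Outlier filter for specimen-level brain data
#'
#' Implements a two-tier allometric plausibility filter. For species with at
#' least `min_specimens` specimens, log10 brain mass is regressed on log10
#' body mass within the species and the species is removed if any specimen's
#' ratio of observed to predicted log10 brain mass falls outside
#' `species_bounds` (default \[0.8, 1.2\]). Species with fewer specimens are
#' judged against a within-genus regression fitted to the genus' other
#' species (the focal species is held out so its own error cannot pull
#' the reference fit) with the wider `genus_bounds` (default
#' \[0.6, 1.7\]), using the species' mean ratio; the genus regression
#' requires at least `min_genus_species` other species with data,
#' otherwise the species is passed through flagged `"unfilterable"`
#' (never silently dropped).
#'
#' @param specimens Data frame with columns `species`, `genus`,
#'   `body_mass_g`, `brain_mass_g` (one row per specimen).
#' @param species_bounds,genus_bounds Length-2 numeric ratio bounds.
#' @param min_specimens Minimum specimens for the species-level rule.
#' @param min_genus_species Minimum species in a genus for the genus rule
#'   (a 2-point regression fits perfectly and filters nothing).
#' @return List with `kept` and `removed` specimen data frames and a
#'   `report` data frame (species, rule, ratio, decision).
#' @export
qc_filter_brain <- function(specimens,
                            species_bounds = c(0.8, 1.2),
                            genus_bounds = c(0.6, 1.7),
                            min_specimens = 5,
                            min_genus_species = 3) {
  req <- c("species", "genus", "body_mass_g", "brain_mass_g")
  if (!all(req %in% names(specimens))) {
    stop("specimens must have columns: ", paste(req, collapse = ", "))
  }
  if (any(specimens$body_mass_g <= 0) || any(specimens$brain_mass_g <= 0)) {
    stop("masses must be positive")
  }
  specimens$.lb <- log10(specimens$body_mass_g)
  specimens$.lbr <- log10(specimens$brain_mass_g)

  sp_split <- split(specimens, specimens$species)
  report <- do.call(rbind, lapply(names(sp_split), function(sp) {
    d <- sp_split[[sp]]
    if (nrow(d) >= min_specimens) {
      pred <- allometric_prediction(d$.lbr, d$.lb)
      ratios <- d$.lbr / pred
      bad <- ratios < species_bounds[1] | ratios > species_bounds[2]
      worst <- ratios[which.max(abs(ratios - 1))]
      data.frame(species = sp, rule = "species", ratio = worst,
                 decision = if (any(bad)) "removed" else "kept",
                 stringsAsFactors = FALSE)
    } else {
      # judge against the rest of the genus (the focal species is held
      # out so its own error cannot drag the reference regression)
      g <- specimens[specimens$genus == d$genus[1] &
                       specimens$species != sp, , drop = FALSE]
      if (length(unique(g$species)) < min_genus_species) {
        data.frame(species = sp, rule = "unfilterable", ratio = NA_real_,
                   decision = "kept", stringsAsFactors = FALSE)
      } else {
        cf <- allometric_coef(g$.lbr, g$.lb)
        pred <- cf[1] + cf[2] * d$.lb
        ratio <- mean(d$.lbr / pred)
        bad <- ratio < genus_bounds[1] | ratio > genus_bounds[2]
        data.frame(species = sp, rule = "genus", ratio = ratio,
                   decision = if (bad) "removed" else "kept",
                   stringsAsFactors = FALSE)
      }
    }
  }))
  rownames(report) <- NULL
  removed_sp <- report$species[report$decision == "removed"]
  keep_cols <- setdiff(names(specimens), c(".lb", ".lbr"))
  list(
    kept = specimens[!specimens$species %in% removed_sp, keep_cols,
                     drop = FALSE],
    removed = specimens[specimens$species %in% removed_sp, keep_cols,
                        drop = FALSE],
    report = report
  )
}

# fitted values of a log-brain on log-body regression; falls back to the
# mean when body mass carries no information
allometric_prediction <- function(lbrain, lbody) {
  if (length(unique(lbody)) < 2) return(rep(mean(lbrain), length(lbrain)))
  unname(fitted(lm(lbrain ~ lbody)))
}

# (intercept, slope) of the same regression, for out-of-sample prediction
allometric_coef <- function(lbrain, lbody) {
  if (length(unique(lbody)) < 2) return(c(mean(lbrain), 0))
  unname(coef(lm(lbrain ~ lbody)))
}

#' Average BMR records within a body-mass window
#'
#' Averages basal metabolic rate only over records whose body mass lies
#' within +/-20% (by default) of the species-specific mean mass, to reduce
#' within-species variability.
#'
#' @param body_mass_g,bmr Paired record vectors (>= 1 record).
#' @param species_mean_mass_g The species mean body mass.
#' @param window Relative half-width of the admissible window.
#' @return List with `bmr_mean` and `n_used`.
#' @export
average_bmr <- function(body_mass_g, bmr, species_mean_mass_g,
                        window = 0.2) {
  if (length(body_mass_g) != length(bmr)) stop("record vectors must align")
  if (length(bmr) == 0) stop("no BMR records supplied")
  keep <- body_mass_g >= (1 - window) * species_mean_mass_g &
    body_mass_g <= (1 + window) * species_mean_mass_g
  if (!any(keep)) {
    stop("no BMR record within +/-", window * 100,
         "% of the species mean mass (", species_mean_mass_g, " g)")
  }
  list(bmr_mean = mean(bmr[keep]), n_used = sum(keep))
}

#' Residuals from an ordinary least-squares regression on body mass
#'
#' Returns OLS residuals of `y` on `x` (with intercept); used to build
#' residual BMR, brain and newborn size before path analysis.
#'
#' @param y,x Equal-length numeric vectors (n >= 3).
#' @return Residual vector (orthogonal to `x`, summing to zero).
#' @export
residualize <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("zero variance in x: regression undefined")
  unname(resid(lm(y ~ x)))
}

# ---- Model-frame preparation ------------------------------------------------

#' Prepare a transformed, scaled model frame
#'
#' Applies log10 to the requested mass variables first, then z-scores
#' (mean 0, population SD 1, so \{1, 2, 3\} maps to +/-1.2247, 0);
#' interaction columns are products of the scaled columns.
#' Rows with any missing requested variable are dropped and the count
#' recorded. Egg-care levels become an unordered factor with `"abandon"` as
#' reference (ordering kept only for presentation).
#'
#' @param table Data frame with a `species` column and the requested trait
#'   columns.
#' @param variables Character vector of columns to keep (besides
#'   `species`).
#' @param log10_vars Variables to log10-transform (must be positive).
#' @param zscore `TRUE` to z-score all numeric variables, `FALSE` for
#'   none, or a character vector naming the variables to scale.
#' @param interactions Character vector of `"a:b"` interaction terms built
#'   from the transformed/scaled columns.
#' @param taxa_order Optional species order for the output rows (e.g. a
#'   covariance matrix's taxa order).
#' @return Data frame (rownames = species) with attributes `n_dropped`,
#'   `scaling` (per-variable centers/scales) and `taxa_order`.
#' @export
prepare_model_frame <- function(table, variables,
                                log10_vars = character(0),
                                zscore = TRUE,
                                interactions = character(0),
                                taxa_order = NULL) {
  stopifnot("species" %in% names(table))
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars)) {
    stop("variables absent from table: ", paste(missing_vars, collapse = ", "))
  }
  df <- table[, c("species", variables), drop = FALSE]
  cc <- complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (anyDuplicated(df$species)) stop("duplicate species in table")

  for (v in log10_vars) {
    if (!v %in% variables) stop("log10 variable not requested: ", v)
    if (any(df[[v]] <= 0)) stop("non-positive values in '", v,
                                "' cannot be log10-transformed")
    df[[v]] <- log10(df[[v]])
  }
  if ("care_level" %in% variables) {
    df$care_level <- factor(as.character(df$care_level),
                            levels = c("abandon", "guard", "bear",
                                       "provision"))
    if (anyNA(df$care_level)) stop("unknown care_level categories")
  }

  num_vars <- variables[vapply(df[variables], is.numeric, logical(1))]
  scale_vars <- if (isTRUE(zscore)) num_vars
  else if (is.character(zscore)) intersect(zscore, num_vars)
  else character(0)
  centers <- setNames(numeric(0), character(0))
  scales <- setNames(numeric(0), character(0))
  for (v in scale_vars) {
    # population-SD normalization: mean 0, root-mean-square deviation 1
    s <- sqrt(mean((df[[v]] - mean(df[[v]]))^2))
    if (s == 0) stop("zero variance in '", v, "': cannot z-score")
    centers[v] <- mean(df[[v]]); scales[v] <- s
    df[[v]] <- (df[[v]] - centers[v]) / s
  }
  for (term in interactions) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% variables)) {
      stop("interaction term '", term, "' must name two requested variables")
    }
    df[[term]] <- df[[parts[1]]] * df[[parts[2]]]
  }
  if (!is.null(taxa_order)) {
    missing_sp <- setdiff(taxa_order, df$species)
    if (length(missing_sp)) {
      stop("taxa_order species absent from frame: ",
           paste(head(missing_sp, 5), collapse = ", "),
           if (length(missing_sp) > 5) " ..." else "")
    }
    df <- df[match(taxa_order, df$species), , drop = FALSE]
  }
  rownames(df) <- df$species
  structure(df, n_dropped = n_dropped,
            scaling = list(center = centers, scale = scales),
            taxa_order = df$species)
}
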