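# Virtual healthy-volunteer population: reproducible between-subject
# variability on demographics, physiology and enzymology.

# Lognormal draw preserving the nominal value as the geometric mean.
# cv is the coefficient of variation of the lognormal; sdlog = sqrt(log(1+cv^2)).
rlnorm_gm <- function(n, gm, cv) {
  if (cv <= 0) return(rep(gm, n))
  gm * exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Sample a virtual population
#'
#' Draws `n` individuals for a study design: sex assignment honouring the
#' design's female proportion exactly (deterministic counts, randomized
#' order), age uniform within the design range, body weight lognormal by sex,
#' then a subject-specific system parameter set - the reference system scaled
#' to the subject's weight with lognormal between-subject variability applied
#' to enzyme abundances, blood flows, organ sizes and microsomal scaling.
#' Nominal values are preserved as geometric means. With all CVs zero, every
#' individual equals the defaults scaled only by their demographics.
#'
#' @param design A [study_design()] (its `population` block supplies `n`,
#'   `age_range`, `prop_female`), or a list with those fields.
#' @param defaults Reference system parameters, see [default_system()].
#' @param cv_spec Named list of coefficients of variation overriding the
#'   system file's `cv` block. Recognized names: `abundance`, `flows`,
#'   `organ_sizes`, `mppgl`, `vss`, `ka`.
#' @param seed Integer seed; identical inputs give a bit-identical population.
#' @return List of individuals, each a list with `id`, `sex`, `age`, `weight`,
#'   `system` (subject-specific `pbpk_system`) and `scalars` (subject's
#'   compound-parameter multipliers for `vss` and `ka`).
#' @export
sample_population <- function(design, defaults = default_system(),
                              cv_spec = NULL, seed = 1L) {
  pop <- if (!is.null(design$population)) design$population else design
  n <- pop$n
  stopifnot(is.numeric(n), n >= 1)
  age <- pop$age_range %||% c(20, 50)
  if (length(age) != 2 || age[1] > age[2] || age[1] < 0) {
    stop("invalid age range")
  }
  pf <- pop$prop_female %||% 0.5
  cv <- utils::modifyList(defaults$cv %||% list(), cv_spec %||% list())
  cv0 <- function(key) cv[[key]] %||% 0

  n_f <- round(n * pf)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
  lapply(seq_len(n), function(i) {
    dem <- if (sex[i] == "F") defaults$demographics$weight_female
           else defaults$demographics$weight_male
    wt <- rlnorm_gm(1, dem$gm, dem$cv)
    subject_age <- stats::runif(1, age[1], age[2])
    sys <- scale_system(defaults, wt)
    fl <- cv0("flows"); sz <- cv0("organ_sizes")
    for (f in c("q_hepatic", "q_kidney", "q_villous")) {
      sys[[f]] <- rlnorm_gm(1, sys[[f]], fl)
    }
    for (f in c("liver_weight", "liver_volume", "kidney_weight",
                "enterocyte_volume")) {
      sys[[f]] <- rlnorm_gm(1, sys[[f]], sz)
    }
    sys$mppgl <- rlnorm_gm(1, sys$mppgl, cv0("mppgl"))
    # Abundance variability is stored as multiplicative factors so that
    # compound-level pool overrides (e.g. a user-defined intestinal UGT pool)
    # inherit the subject's draw even when the system nominal value is zero.
    abcv <- cv0("abundance")
    sys$ab_factor <- lapply(sys$abundance, function(e) {
      list(liver = rlnorm_gm(1, 1, abcv),
           intestine = rlnorm_gm(1, 1, abcv),
           kidney = rlnorm_gm(1, 1, abcv))
    })
    for (e in names(sys$abundance)) {
      for (tis in c("liver", "intestine", "kidney")) {
        sys$abundance[[e]][[tis]] <-
          sys$abundance[[e]][[tis]] * sys$ab_factor[[e]][[tis]]
      }
    }
    list(id = i, sex = sex[i], age = subject_age, weight = wt,
         system = sys,
         scalars = list(vss = rlnorm_gm(1, 1, cv0("vss")),
                        ka = rlnorm_gm(1, 1, cv0("ka"))))
  })
}

#' Effective tissue abundance for one sampled individual
#'
#' @param individual An element of [sample_population()].
#' @param enzyme,tissue Enzyme name and tissue (`"liver"`, `"intestine"`,
#'   `"kidney"`).
#' @return The subject's effective abundance (liver/kidney pmol/mg, intestine
#'   pmol total).
#' @export
subject_abundance <- function(individual, enzyme, tissue) {
  individual$system$abundance[[enzyme]][[tissue]]
}

#' Population-mean individual
#'
#' The deterministic reference subject: all between-subject variability
#' removed, demographics at the reference body weight.
#'
#' @param defaults Reference system parameters.
#' @param weight Body weight, kg (default: the system reference weight).
#' @return A single individual in the [sample_population()] format.
#' @export
mean_individual <- function(defaults = default_system(), weight = NULL) {
  wt <- weight %||% defaults$body_weight_ref
  list(id = 0L, sex = "M", age = 35, weight = wt,
       system = scale_system(defaults, wt),
       scalars = list(vss = 1, ka = 1))
}
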