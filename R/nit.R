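logistic <- function(x) 1 / (1 + exp(-x))

#' AST-to-platelet ratio index (APRI)
#'
#' `APRI = (AST / AST_ULN) * 100 / platelets`.
#'
#' @param ast AST in U/L.
#' @param ast_uln Upper limit of normal for AST in U/L (default 40).
#' @param platelets Platelet count in 10^9/L.
#' @return APRI (vectorized).
#' @export
score_apri <- function(ast, platelets, ast_uln = 40) {
  if (any(ast_uln <= 0) || any(platelets <= 0)) {
    stop("ast_uln and platelets must be positive", call. = FALSE)
  }
  (ast / ast_uln) * 100 / platelets
}

#' AST-to-ALT ratio (AAR)
#'
#' @param ast AST in U/L.
#' @param alt ALT in U/L (must be positive).
#' @return AAR (vectorized).
#' @export
score_aar <- function(ast, alt) {
  if (any(alt <= 0)) stop("alt must be positive", call. = FALSE)
  ast / alt
}

#' Fibrosis-4 index (FIB-4)
#'
#' The `"standard"` variant is the established published form
#' `age * AST / (platelets * sqrt(ALT))`. The `"as_printed"` variant
#' uses `ALT` unrooted (`age * AST / (platelets * ALT)`), matching a
#' formula transcription in which the square root is lost; it is kept
#' for comparison only.
#'
#' @param age Age in years.
#' @param ast,alt AST and ALT in U/L.
#' @param platelets Platelet count in 10^9/L.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return FIB-4 (vectorized).
#' @export
score_fib4 <- function(age, ast, alt, platelets,
                       variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (any(alt <= 0) || any(platelets <= 0)) {
    stop("alt and platelets must be positive", call. = FALSE)
  }
  denom_alt <- if (variant == "standard") sqrt(alt) else alt
  age * ast / (platelets * denom_alt)
}

#' NAFLD fibrosis score (NFS)
#'
#' `NFS = -1.675 + 0.037*Age + 0.094*BMI + 1.13*IFG/diabetes
#'  + 0.99*AST/ALT - 0.013*platelets - 0.66*albumin`.
#' The `"indicator"` variant (default) multiplies 1.13 by the binary
#' impaired-fasting-glycemia / diabetes flag, the established form. The
#' `"as_printed"` variant multiplies glucose in mmol/L instead, as in a
#' transcription that renders the indicator as a concentration; its
#' output is shifted by several points and is kept for comparison only.
#'
#' @param age Age in years.
#' @param bmi Body-mass index in kg/m^2.
#' @param hyperglycemia Binary IFG/diabetes flag (indicator variant).
#' @param glucose Fasting glucose in mmol/L (as-printed variant).
#' @param ast,alt AST and ALT in U/L.
#' @param platelets Platelet count in 10^9/L.
#' @param albumin_gdl Albumin in g/dL.
#' @param variant `"indicator"` (default) or `"as_printed"`.
#' @return NFS (vectorized).
#' @export
score_nfs <- function(age, bmi, ast, alt, platelets, albumin_gdl,
                      hyperglycemia = NULL, glucose = NULL,
                      variant = c("indicator", "as_printed")) {
  variant <- match.arg(variant)
  if (any(alt <= 0)) stop("alt must be positive", call. = FALSE)
  gly <- if (variant == "indicator") {
    if (is.null(hyperglycemia)) {
      stop("hyperglycemia flag required for the indicator variant",
           call. = FALSE)
    }
    as.numeric(hyperglycemia)
  } else {
    if (is.null(glucose)) {
      stop("glucose required for the as_printed variant", call. = FALSE)
    }
    glucose
  }
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * gly + 0.99 * (ast / alt) -
    0.013 * platelets - 0.66 * albumin_gdl
}

#' FibroScan-AST score (FAST)
#'
#' Linear predictor
#' `x = -1.65 + 1.07*ln(LSM) + 2.66e-8*CAP^3 - 63.3/AST`, returned
#' through the logistic link by default so the score lies in (0, 1),
#' consistent with its published probability scale.
#'
#' @param vcte_lsm VCTE liver stiffness in kPa.
#' @param cap Controlled attenuation parameter in dB/m.
#' @param ast AST in U/L.
#' @param logistic_link Apply the logistic transform (default `TRUE`).
#' @return FAST (vectorized).
#' @export
score_fast <- function(vcte_lsm, cap, ast, logistic_link = TRUE) {
  if (any(vcte_lsm <= 0) || any(ast <= 0)) {
    stop("vcte_lsm and ast must be positive", call. = FALSE)
  }
  x <- -1.65 + 1.07 * log(vcte_lsm) + 2.66e-8 * cap^3 - 63.3 / ast
  if (logistic_link) logistic(x) else x
}

#' MRI-AST score (MAST)
#'
#' Linear predictor
#' `x = -12.17 + 7.07*log10(MRE) + 0.037*PDFF + 3.55*log10(AST)`,
#' returned through the logistic link by default. Base-10 logs are used:
#' with natural logs the predictor saturates the logistic near 1 for
#' typical MASLD inputs, while base-10 reproduces the score's published
#' magnitude (cohort medians near 0.1-0.3).
#'
#' @param mre_lsm MRE liver stiffness in kPa.
#' @param pdff Proton-density fat fraction in %.
#' @param ast AST in U/L.
#' @param logistic_link Apply the logistic transform (default `TRUE`).
#' @param log_base Base of the logarithms (default 10).
#' @return MAST (vectorized).
#' @export
score_mast <- function(mre_lsm, pdff, ast, logistic_link = TRUE,
                       log_base = 10) {
  if (any(mre_lsm <= 0) || any(ast <= 0)) {
    stop("mre_lsm and ast must be positive", call. = FALSE)
  }
  x <- -12.17 + 7.07 * log(mre_lsm, base = log_base) + 0.037 * pdff +
    3.55 * log(ast, base = log_base)
  if (logistic_link) logistic(x) else x
}

#' Compute the non-invasive test panel for a cohort
#'
#' Appends the six composite scores (MAST, FAST, FIB-4, APRI, AAR, NFS)
#' to a cohort tibble; MRE-LSM and VCTE-LSM pass through as measured
#' inputs. A score whose inputs are missing for a patient is set to `NA`
#' rather than failing; the formula variants used are recorded in the
#' `variants` attribute.
#'
#' @param cohort Tibble with columns as produced by [generate_cohort()]
#'   (`age`, `bmi`, `ast`, `alt`, `plt`, `alb_gl` in g/L, `glucose`,
#'   `hyperglycemia`, `cap`, `vcte_lsm`, `mre_lsm`, `pdff`, `ast_uln`).
#' @param fib4_variant,nfs_variant Formula variants (see [score_fib4()],
#'   [score_nfs()]).
#' @param logistic_link Logistic transform for FAST and MAST (default
#'   `TRUE`).
#' @return `cohort` with columns `mast`, `fast`, `fib4`, `apri`, `aar`,
#'   `nfs` appended.
#' @export
compute_nit_panel <- function(cohort, fib4_variant = "standard",
                              nfs_variant = "indicator",
                              logistic_link = TRUE) {
  cohort <- tibble::as_tibble(cohort)
  ast_uln <- if ("ast_uln" %in% names(cohort)) cohort$ast_uln else 40
  per_score <- function(needed, f) {
    ok <- Reduce(`&`, lapply(needed, function(cn) {
      if (!cn %in% names(cohort)) rep(FALSE, nrow(cohort)) else
        !is.na(cohort[[cn]])
    }))
    out <- rep(NA_real_, nrow(cohort))
    if (any(ok)) out[ok] <- f(ok)
    out
  }
  cohort$mast <- per_score(c("mre_lsm", "pdff", "ast"), function(ok) {
    score_mast(cohort$mre_lsm[ok], cohort$pdff[ok], cohort$ast[ok],
               logistic_link = logistic_link)
  })
  cohort$fast <- per_score(c("vcte_lsm", "cap", "ast"), function(ok) {
    score_fast(cohort$vcte_lsm[ok], cohort$cap[ok], cohort$ast[ok],
               logistic_link = logistic_link)
  })
  cohort$fib4 <- per_score(c("age", "ast", "alt", "plt"), function(ok) {
    score_fib4(cohort$age[ok], cohort$ast[ok], cohort$alt[ok],
               cohort$plt[ok], variant = fib4_variant)
  })
  cohort$apri <- per_score(c("ast", "plt"), function(ok) {
    score_apri(cohort$ast[ok], cohort$plt[ok],
               ast_uln = if (length(ast_uln) > 1) ast_uln[ok] else ast_uln)
  })
  cohort$aar <- per_score(c("ast", "alt"), function(ok) {
    score_aar(cohort$ast[ok], cohort$alt[ok])
  })
  cohort$nfs <- per_score(
    c("age", "bmi", "ast", "alt", "plt", "alb_gl", "hyperglycemia"),
    function(ok) {
      score_nfs(cohort$age[ok], cohort$bmi[ok], cohort$ast[ok],
                cohort$alt[ok], cohort$plt[ok],
                albumin_gdl = cohort$alb_gl[ok] / 10, # g/L -> g/dL
                hyperglycemia = cohort$hyperglycemia[ok],
                glucose = if ("glucose" %in% names(cohort))
                  cohort$glucose[ok] else NULL,
                variant = nfs_variant)
    }
  )
  attr(cohort, "variants") <- list(
    fib4 = fib4_variant, nfs = nfs_variant,
    logistic_link = logistic_link, mast_log_base = 10
  )
  cohort
}
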