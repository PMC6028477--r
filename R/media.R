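# Salt-to-ion stoichiometry for macronutrient culture-medium formulations.
#
# The rooting experiment varied four macronutrient salts (KNO3, NH4NO3,
# Ca(NO3)2.4H2O, CaCl2.2H2O) across 36 media; the network models take the
# resulting five ion concentrations (NO3-, NH4+, K+, Ca2+, Cl-) in mM as
# inputs. Converting mg/L of salt to mM of ion is mass / molar mass, with
# nitrate accumulating from all three nitrate salts.

#' Molar masses of the macronutrient salts
#'
#' Default molar masses (g/mol) used to convert salt masses to ion
#' molarities. Calcium nitrate is the tetrahydrate and calcium chloride the
#' dihydrate: these hydrate identities are the ones consistent with the
#' published ion table (e.g. 440 mg/L CaCl2.2H2O -> 3.00 mM Ca2+).
#'
#' @return Named numeric vector with entries `kno3`, `nh4no3`,
#'   `cano3_2_4h2o`, `cacl2_2h2o`.
#' @examples
#' macronutrient_molar_masses()
#' @export
macronutrient_molar_masses <- function() {
  c(kno3 = 101.10, nh4no3 = 80.04, cano3_2_4h2o = 236.15, cacl2_2h2o = 147.02)
}

salt_cols <- function() c("kno3_mg_l", "nh4no3_mg_l", "cano3_2_4h2o_mg_l",
                          "cacl2_2h2o_mg_l")

check_molar_masses <- function(masses) {
  needed <- names(macronutrient_molar_masses())
  if (!is.numeric(masses) || is.null(names(masses))) {
    stop("'masses' must be a named numeric vector of molar masses", call. = FALSE)
  }
  unknown <- setdiff(names(masses), needed)
  if (length(unknown)) {
    stop(sprintf("unknown salt(s) in molar mass table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(needed, names(masses))
  if (length(missing)) {
    stop(sprintf("molar mass table is missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all molar masses must be positive and finite", call. = FALSE)
  }
  masses[needed]
}

#' Convert salt formulations to ion concentrations
#'
#' Converts macronutrient salt masses (mg/L) into the five-ion profile
#' (NO3-, NH4+, K+, Ca2+, Cl-) in mM. Nitrate sums contributions from
#' KNO3, NH4NO3 and Ca(NO3)2 (two NO3- per formula unit); calcium sums the
#' nitrate and chloride salts.
#'
#' Two conventions are offered for chloride. The published ion table reports
#' Cl- equal to the molarity of CaCl2.2H2O (one Cl- per formula unit);
#' `cl_convention = "per_salt"` reproduces that table and is the default.
#' Stoichiometrically CaCl2 dissociates to two Cl-, which
#' `cl_convention = "stoichiometric"` implements. Whether the factor-two
#' difference in the source table is typographic cannot be settled from the
#' data, so both are exposed; all modelling downstream uses `per_salt` so
#' model inputs match the table the responses were measured against.
#'
#' @param formulations Data frame with columns `code`, `kno3_mg_l`,
#'   `nh4no3_mg_l`, `cano3_2_4h2o_mg_l`, `cacl2_2h2o_mg_l` (one row per
#'   medium), e.g. from [load_formulations()].
#' @param masses Named vector of molar masses, see
#'   [macronutrient_molar_masses()].
#' @param cl_convention `"per_salt"` (default; matches the published table)
#'   or `"stoichiometric"` (2 Cl- per CaCl2).
#' @return Data frame with columns `code`, `no3`, `nh4`, `k`, `ca`, `cl`
#'   (mM, unrounded).
#' @examples
#' m <- data.frame(code = 1, kno3_mg_l = 1900, nh4no3_mg_l = 1650,
#'                 cano3_2_4h2o_mg_l = 556, cacl2_2h2o_mg_l = 0)
#' round(ions_from_salts(m)[-1], 2)  # 44.12, 20.62, 18.79, 2.35, 0
#' @export
ions_from_salts <- function(formulations,
                            masses = macronutrient_molar_masses(),
                            cl_convention = c("per_salt", "stoichiometric")) {
  cl_convention <- match.arg(cl_convention)
  masses <- check_molar_masses(masses)
  stopifnot_cols(formulations, c("code", salt_cols()), "formulations")
  sm <- as.matrix(formulations[salt_cols()])
  if (!is.numeric(sm) || any(!is.finite(sm))) {
    stop("salt masses must be finite numbers", call. = FALSE)
  }
  if (any(sm < 0)) {
    stop(sprintf("negative salt mass in row(s): %s",
                 paste(which(rowSums(sm < 0) > 0), collapse = ", ")),
         call. = FALSE)
  }
  kno3 <- sm[, "kno3_mg_l"] / masses[["kno3"]]
  nh4no3 <- sm[, "nh4no3_mg_l"] / masses[["nh4no3"]]
  cano3 <- sm[, "cano3_2_4h2o_mg_l"] / masses[["cano3_2_4h2o"]]
  cacl2 <- sm[, "cacl2_2h2o_mg_l"] / masses[["cacl2_2h2o"]]
  data.frame(
    code = formulations$code,
    no3 = kno3 + nh4no3 + 2 * cano3,
    nh4 = nh4no3,
    k = kno3,
    ca = cano3 + cacl2,
    cl = if (cl_convention == "per_salt") cacl2 else 2 * cacl2,
    row.names = NULL
  )
}

#' Load macronutrient salt formulations from CSV
#'
#' Reads a formulation table (one medium per row) and validates it: all
#' required columns present, codes unique, masses numeric and non-negative.
#'
#' @param path Path to a CSV with header
#'   `code,kno3_mg_l,nh4no3_mg_l,cano3_2_4h2o_mg_l,cacl2_2h2o_mg_l`.
#' @return Data frame of formulations, input order preserved.
#' @seealso [gn15_media()] for the packaged 36-medium fixture.
#' @export
load_formulations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stopifnot_cols(df, c("code", salt_cols()), sprintf("'%s'", path))
    return(df)
  }
  stopifnot_cols(df, c("code", salt_cols()), sprintf("'%s'", path))
  for (col in salt_cols()) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric mass in column '%s', row(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- as.numeric(df[[col]])
    neg <- which(df[[col]] < 0)
    if (length(neg)) {
      stop(sprintf("negative mass in column '%s', row(s): %s", col,
                   paste(neg, collapse = ", ")), call. = FALSE)
    }
  }
  dup <- df$code[duplicated(df$code)]
  if (length(dup)) {
    stop(sprintf("duplicate medium code(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Cross-check recomputed ion profiles against a reference table
#'
#' Recomputes ion concentrations from salt masses and compares them to a
#' reference ion table medium by medium, flagging any |difference| above
#' `tol`. Used to confirm that the packaged salt table reproduces the
#' published ion table.
#'
#' @param formulations Salt formulations, as for [ions_from_salts()].
#' @param reference_ions Data frame with columns `code`, `no3`, `nh4`, `k`,
#'   `ca`, `cl` (mM).
#' @param tol Absolute tolerance in mM (default 0.02, i.e. the rounding
#'   resolution of a 2-decimal table).
#' @param masses,cl_convention Passed to [ions_from_salts()].
#' @return Data frame with one row per medium x ion: `code`, `ion`,
#'   `reference`, `computed`, `diff`, `flag` (logical). Attribute
#'   `n_flagged` gives the total number of flags.
#' @export
verify_against_reference <- function(formulations, reference_ions, tol = 0.02,
                                     masses = macronutrient_molar_masses(),
                                     cl_convention = c("per_salt", "stoichiometric")) {
  stopifnot_cols(reference_ions, c("code", ion_names()), "reference_ions")
  if (nrow(formulations) != nrow(reference_ions)) {
    stop("formulations and reference_ions must have the same number of rows",
         call. = FALSE)
  }
  if (!identical(as.integer(formulations$code), as.integer(reference_ions$code))) {
    stop("medium codes of formulations and reference_ions do not match",
         call. = FALSE)
  }
  computed <- ions_from_salts(formulations, masses, cl_convention)
  out <- do.call(rbind, lapply(ion_names(), function(ion) {
    data.frame(code = computed$code, ion = ion,
               reference = reference_ions[[ion]], computed = computed[[ion]],
               diff = abs(computed[[ion]] - reference_ions[[ion]]),
               row.names = NULL)
  }))
  out$flag <- out$diff > tol
  out <- out[order(out$code, match(out$ion, ion_names())), ]
  rownames(out) <- NULL
  structure(out, n_flagged = sum(out$flag))
}
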