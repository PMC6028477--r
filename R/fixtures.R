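# Packaged data: the 36-medium macronutrient experiment on G x N15.

#' Macronutrient salt formulations of the 36 rooting media
#'
#' The 36 media of the published macronutrient experiment as salt masses
#' (mg/L). Media 1-18 supply calcium as Ca(NO3)2.4H2O, media 19-36 as
#' CaCl2.2H2O; KNO3 and NH4NO3 take 1, 0.75 and 0.5 fold of the LS basal
#' levels (1900/1425/950 and 1650/1238/825 mg/L).
#'
#' @return Data frame with columns `code`, `kno3_mg_l`, `nh4no3_mg_l`,
#'   `cano3_2_4h2o_mg_l`, `cacl2_2h2o_mg_l`; 36 rows.
#' @seealso [ions_from_salts()], [gn15_treatments()]
#' @export
gn15_media <- function() {
  load_formulations(system.file("extdata", "gn15_salt_formulations.csv",
                                package = "rootnet", mustWork = TRUE))
}

#' Treatment-level rooting responses of the 36 media
#'
#' Ion concentrations (mM) and the five rooting responses of G x N15
#' micro-shoots — root number (RN), root length (RL, cm), rooting
#' percentage (Rpct, proportion in \[0,1\]), root fresh weight (FW, g) and
#' dry weight (DW, g) — as treatment means with standard errors of the mean
#' over `n_reps` replicates (six replicates of four explants each).
#'
#' @return Data frame with columns `code`, `no3`, `nh4`, `k`, `ca`, `cl`
#'   (mM), `<response>_mean` and `<response>_se` for each of `rn`, `rl`,
#'   `rpct`, `fw`, `dw`, and `n_reps`; 36 rows.
#' @seealso [expand_replicates()]
#' @export
gn15_treatments <- function() {
  path <- system.file("extdata", "gn15_rooting_treatments.csv",
                      package = "rootnet", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- sub("_mm$", "", names(df))
  df$n_reps <- 6L
  df
}
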