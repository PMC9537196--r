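# Self-contained fixture documents: small SBtab models with the
# structure of the calcium/dopamine use case (two input cascades
# converging on a phosphorylation readout), plus generators for the
# Delta-t experiment protocol and simulated data tables. Fixtures are
# generated in code, never stored, so the generator and the parser
# co-evolve.

sbtab_table <- function(doc, name, df, type = "Quantity") {
  doc$tables[[name]] <- df
  doc$meta[[name]] <- list(TableName = name, TableType = type,
                           SBtabVersion = "1.0")
  doc
}

df_sbtab <- function(...) data.frame(..., check.names = FALSE,
                                     stringsAsFactors = FALSE)

#' Generate a fixture model document
#'
#' Deterministic per `(kind, seed)`:
#' \describe{
#'   \item{`two_state`}{`A <=> B`, one compartment — the minimal
#'     relaxation model with one conserved total.}
#'   \item{`thermo_triangle`}{the classic Wegscheider cycle
#'     `A <=> B <=> C <=> A`; exactly one thermodynamic constraint.}
#'   \item{`enzyme_cycle`}{`E + S <=> ES`, `ES => E + P`; exactly two
#'     conserved moieties (enzyme and substrate).}
#'   \item{`usecase_like`}{a desk-scale analogue of the eligibility-trace
#'     use case: a calcium-like spike-train input activating a kinase
#'     that phosphorylates a substrate, a dopamine-like transient input
#'     sequestering the opposing phosphatase, 10 species across two
#'     compartments (Spine, PSD), four conserved moieties and one
#'     reversible cycle whose default rates satisfy detailed balance.
#'     Outputs Y0-Y3 report phosphorylated substrate, active kinase,
#'     free phosphatase and bound receptor.}
#' }
#'
#' @param kind fixture kind.
#' @param seed retained for interface stability; the documents are fully
#'   deterministic.
#' @return an `sbtab_document` that passes [validate_sbtab()] with zero
#'   findings.
#' @export
fixture_model <- function(kind = c("two_state", "enzyme_cycle",
                                   "thermo_triangle", "usecase_like"),
                          seed = 1) {
  kind <- match.arg(kind)
  doc <- new_sbtab_document(source = sprintf("fixture:%s:%d", kind, seed))
  switch(kind,
    two_state = {
      doc <- sbtab_table(doc, "Compartment",
                         df_sbtab(`!ID` = "cell", `!Name` = "cell", `!Size` = 1),
                         "Compartment")
      doc <- sbtab_table(doc, "Compound",
                         df_sbtab(`!ID` = c("A", "B"), `!Name` = c("A", "B"),
                                  `!Location` = "cell", `!InitialValue` = c(2, 0)),
                         "Compound")
      doc <- sbtab_table(doc, "Reaction",
                         df_sbtab(`!ID` = "R1", `!Name` = "interconversion",
                                  `!KineticLaw` = "kf_R1*A-kr_R1*B",
                                  `!IsReversible` = "TRUE", `!Location` = "cell",
                                  `!ReactionFormula` = "A <=> B"),
                         "Reaction")
      doc <- sbtab_table(doc, "Parameter",
                         df_sbtab(`!ID` = c("kf_R1", "kr_R1"),
                                  `!DefaultValue` = c(1, 1), `!Unit` = "1/s"),
                         "Quantity")
      doc <- sbtab_table(doc, "Output",
                         df_sbtab(`!ID` = "Y0", `!Name` = "B", `!Formula` = "B"),
                         "Quantity")
      doc
    },
    thermo_triangle = {
      doc <- sbtab_table(doc, "Compartment",
                         df_sbtab(`!ID` = "cell", `!Size` = 1), "Compartment")
      doc <- sbtab_table(doc, "Compound",
                         df_sbtab(`!ID` = c("A", "B", "C"), `!Location` = "cell",
                                  `!InitialValue` = c(3, 0, 0)), "Compound")
      doc <- sbtab_table(doc, "Reaction",
                         df_sbtab(`!ID` = c("R1", "R2", "R3"),
                                  `!KineticLaw` = c("kf_R1*A-kr_R1*B",
                                                    "kf_R2*B-kr_R2*C",
                                                    "kf_R3*C-kr_R3*A"),
                                  `!IsReversible` = "TRUE", `!Location` = "cell",
                                  `!ReactionFormula` = c("A <=> B", "B <=> C",
                                                         "C <=> A")),
                         "Reaction")
      # detailed-balance default: (kf1 kf2 kf3)/(kr1 kr2 kr3) = 1
      doc <- sbtab_table(doc, "Parameter",
                         df_sbtab(`!ID` = c("kf_R1", "kr_R1", "kf_R2", "kr_R2",
                                            "kf_R3", "kr_R3"),
                                  `!DefaultValue` = c(2, 4, 3, 3, 4, 2),
                                  `!Unit` = "1/s"), "Quantity")
      doc
    },
    enzyme_cycle = {
      doc <- sbtab_table(doc, "Compartment",
                         df_sbtab(`!ID` = "cell", `!Size` = 1), "Compartment")
      doc <- sbtab_table(doc, "Compound",
                         df_sbtab(`!ID` = c("E", "S", "ES", "P"),
                                  `!Location` = "cell",
                                  `!InitialValue` = c(10, 100, 0, 0)), "Compound")
      doc <- sbtab_table(doc, "Reaction",
                         df_sbtab(`!ID` = c("R1", "R2"),
                                  `!KineticLaw` = c("kf_R1*E*S-kr_R1*ES",
                                                    "kcat_R2*ES"),
                                  `!IsReversible` = c("TRUE", "FALSE"),
                                  `!Location` = "cell",
                                  `!ReactionFormula` = c("E + S <=> ES",
                                                         "ES => E + P")),
                         "Reaction")
      doc <- sbtab_table(doc, "Parameter",
                         df_sbtab(`!ID` = c("kf_R1", "kr_R1", "kcat_R2"),
                                  `!DefaultValue` = c(0.01, 1, 0.5),
                                  `!Unit` = c("1/(nM*s)", "1/s", "1/s")),
                         "Quantity")
      doc
    },
    usecase_like = {
      doc <- sbtab_table(doc, "Compartment",
                         df_sbtab(`!ID` = c("Spine", "PSD"),
                                  `!Name` = c("spine", "post-synaptic density"),
                                  `!Size` = c(1, 1)), "Compartment")
      doc <- sbtab_table(doc, "Compound", df_sbtab(
        `!ID` = c("K", "K_Ca", "Sub", "SubP", "Rc", "Rc_DA",
                  "Pp", "Pp_i", "Rc_DA_Pp", "Rc_DA_Pp_i"),
        `!Name` = c("kinase", "Ca-activated kinase", "substrate",
                    "phosphorylated substrate", "receptor",
                    "DA-bound receptor", "phosphatase",
                    "inactive phosphatase", "receptor-bound phosphatase",
                    "receptor-bound inactive phosphatase"),
        `!Location` = c("Spine", "Spine", "PSD", "PSD", "Spine", "Spine",
                        "Spine", "Spine", "Spine", "Spine"),
        `!InitialValue` = c(100, 0, 1000, 0, 50, 0, 30, 0, 0, 0)),
        "Compound")
      doc <- sbtab_table(doc, "Reaction", df_sbtab(
        `!ID` = paste0("R", 1:7),
        `!Name` = c("kinase activation by calcium",
                    "receptor binding of dopamine",
                    "substrate (de)phosphorylation",
                    "phosphatase inactivation",
                    "phosphatase sequestration",
                    "inactive phosphatase sequestration",
                    "bound phosphatase inactivation"),
        `!KineticLaw` = c("kf_R1*K*Ca-kr_R1*K_Ca",
                          "kf_R2*Rc*DA-kr_R2*Rc_DA",
                          "kf_R3*K_Ca*Sub-kr_R3*Pp*SubP",
                          "kf_R4*Pp-kr_R4*Pp_i",
                          "kf_R5*Rc_DA*Pp-kr_R5*Rc_DA_Pp",
                          "kf_R6*Rc_DA*Pp_i-kr_R6*Rc_DA_Pp_i",
                          "kf_R7*Rc_DA_Pp-kr_R7*Rc_DA_Pp_i"),
        `!IsReversible` = "TRUE",
        `!Location` = c("Spine", "Spine", "PSD", "Spine", "Spine", "Spine",
                        "Spine"),
        `!ReactionFormula` = c("K <=> K_Ca",
                               "Rc <=> Rc_DA",
                               "Sub <=> SubP",
                               "Pp <=> Pp_i",
                               "Rc_DA + Pp <=> Rc_DA_Pp",
                               "Rc_DA + Pp_i <=> Rc_DA_Pp_i",
                               "Rc_DA_Pp <=> Rc_DA_Pp_i")),
        "Reaction")
      # detailed balance around the R4-R5-R6-R7 cycle:
      # (kf4/kr4) * (kf5/kr5)^-1 * (kf6/kr6) * (kf7/kr7)^-1 = 1
      doc <- sbtab_table(doc, "Parameter", df_sbtab(
        `!ID` = c("kf_R1", "kr_R1", "kf_R2", "kr_R2", "kf_R3", "kr_R3",
                  "kf_R4", "kr_R4", "kf_R5", "kr_R5", "kf_R6", "kr_R6",
                  "kf_R7", "kr_R7"),
        `!DefaultValue` = c(0.002, 5, 0.0015, 1, 0.0002, 0.01,
                            0.1, 0.1, 0.1, 1, 0.1, 1, 0.2, 0.2),
        `!Unit` = c("1/(nM*s)", "1/s", "1/(nM*s)", "1/s", "1/(nM*s)",
                    "1/(nM*s)", "1/s", "1/s", "1/(nM*s)", "1/s",
                    "1/(nM*s)", "1/s", "1/s", "1/s")),
        "Quantity")
      doc <- sbtab_table(doc, "Input", df_sbtab(
        `!ID` = c("Ca", "DA"),
        `!Name` = c("calcium burst", "dopamine transient"),
        `!Kind` = c("spike_train", "double_exponential"),
        `!Amplitude` = c(5000, 1500),
        `!Onset` = c(4, 4),
        `!Count` = c(10, 1),
        `!Frequency` = c(10, 1),
        `!TauRise` = c(0.005, 0.05),
        `!TauDecay` = c(0.05, 0.5),
        `!DefaultValue` = c(0, 0)), "Quantity")
      doc <- sbtab_table(doc, "Expression", df_sbtab(
        `!ID` = "phospho_frac",
        `!Name` = "fraction of phosphorylated substrate",
        `!Formula` = "SubP/(Sub + SubP)"), "Quantity")
      doc <- sbtab_table(doc, "Output", df_sbtab(
        `!ID` = c("Y0", "Y1", "Y2", "Y3"),
        `!Name` = c("phosphorylated substrate", "active kinase",
                    "free phosphatase", "bound receptor"),
        `!Formula` = c("SubP", "K_Ca", "Pp", "Rc_DA")), "Quantity")
      doc
    })
}

#' Add the Delta-t experiment protocol to a fixture document
#'
#' One Experiments row per relative dopamine timing `Delta t` (dopamine
#' onset = calcium onset + `Delta t`), in `dt_list` order starting with
#' the most negative offset, plus optionally one calcium-only experiment
#' with the dopamine amplitude set to zero. Ids are `E0 ... En`.
#'
#' @param doc a fixture document with both input channels (`Ca`, `DA`).
#' @param dt_list relative timings in seconds. Default `-4:4`.
#' @param include_no_dopamine append the calcium-only experiment.
#'   Default `TRUE`.
#' @param ca_onset calcium burst onset (s). Default 4.
#' @return the document with an Experiments table added.
#' @export
fixture_experiments <- function(doc, dt_list = -4:4, include_no_dopamine = TRUE,
                                ca_onset = 4) {
  stopifnot(inherits(doc, "sbtab_document"))
  if (!"Input" %in% names(doc$tables)) {
    abort_sbtab("document has no Input table; experiments need input channels",
                "sbtab_validation_error")
  }
  n_dt <- length(dt_list)
  n <- n_dt + as.integer(include_no_dopamine)
  if (!n) return(sbtab_table(doc, "Experiments",
                             df_sbtab(`!ID` = character(),
                                      `!Name` = character()), "Quantity"))
  ids <- paste0("E", seq_len(n) - 1L)
  onset <- c(ca_onset + dt_list, if (include_no_dopamine) ca_onset)
  amp <- c(rep(NA_real_, n_dt), if (include_no_dopamine) 0)
  note <- c(sprintf("dopamine offset %+d s relative to calcium", dt_list),
            if (include_no_dopamine) "calcium only (no dopamine input)")
  exps <- df_sbtab(`!ID` = ids, `!Name` = note,
                   `>DA:Onset` = onset, `>DA:Amplitude` = amp)
  sbtab_table(doc, "Experiments", exps, "Quantity")
}

#' Generate simulated data tables for every experiment
#'
#' Simulates each experiment of `doc` at `theta` on `[0, window]` with
#' the given output step, adds Gaussian noise of standard deviation
#' `noise_sd * tau` (so `noise_sd = 0` gives data the objective scores
#' exactly zero at `theta`), fills the `SD_` columns with `tau`, and
#' appends one data table per experiment.
#'
#' @param doc document with Experiments table (see
#'   [fixture_experiments()]).
#' @param theta named parameter vector; default Parameter-table values.
#' @param window data window length (s). Default 20.
#' @param step sampling step (s). Default 0.01 (2001 points for a 20 s
#'   window).
#' @param noise_sd noise level as a multiple of `tau`. Default 0.
#' @param tau allowed mismatch filled into the `SD_` columns. Default 1.
#' @param seed RNG seed for the noise. Default 1.
#' @param settings solver settings.
#' @return the document with per-experiment data tables appended.
#' @export
fixture_data <- function(doc, theta = NULL, window = 20, step = 0.01,
                         noise_sd = 0, tau = 1, seed = 1, settings = list()) {
  stopifnot(inherits(doc, "sbtab_document"))
  network <- build_network(doc)
  model <- compile_model(network)
  results <- run_all_experiments(model, doc, theta, window = c(0, window),
                                 times = seq(0, window, by = step),
                                 settings = settings)
  if (length(attr(results, "failures"))) {
    abort_sbtab(sprintf("fixture simulation failed for: %s",
                        paste(attr(results, "failures"), collapse = ", ")),
                "sbtab_simulation_error")
  }
  set.seed(seed)
  for (id in names(results)) {
    res <- results[[id]]
    df <- result_as_data_table(res, sd_value = tau)
    if (noise_sd > 0) {
      for (cn in grep("^>", names(df), value = TRUE)) {
        df[[cn]] <- df[[cn]] + stats::rnorm(nrow(df), 0, noise_sd * tau)
      }
    }
    doc <- sbtab_table(doc, id, df, "QuantityMatrix")
  }
  doc
}
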