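# Mitochondrial metabolite names used as non-binding library members of the
# phosphate-carrier screen fixture (ground-truth shift 0). The four genuine
# hits are prepended in builtinScenarios(); names here are only labels.
.MITO_DECOYS <- c(
  "alanine", "arginine", "asparagine", "aspartate", "cysteine", "glutamate",
  "glutamine", "glycine", "histidine", "isoleucine", "leucine", "lysine",
  "methionine", "phenylalanine", "proline", "serine", "threonine",
  "tryptophan", "tyrosine", "valine", "ornithine", "citrulline", "creatine",
  "carnitine", "acetyl-carnitine", "taurine", "urea", "citrate",
  "isocitrate", "cis-aconitate", "2-oxoglutarate", "succinate", "fumarate",
  "malate", "oxaloacetate", "pyruvate", "lactate", "glyoxylate-amide",
  "acetate", "propionate", "butyrate", "malonate", "oxalate", "glutarate",
  "adipate", "citramalate", "itaconate", "mesaconate", "tartrate",
  "alpha-ketobutyrate", "beta-hydroxybutyrate", "acetoacetate",
  "glycerate", "glycolate", "glycerol", "myo-inositol", "choline",
  "ethanolamine", "serine-phosphoglycerol", "dihydroxyacetone",
  "ribose", "ribulose", "xylulose", "erythrose", "sedoheptulose",
  "glucose", "fructose", "galactose", "mannose", "trehalose", "maltose",
  "sucrose", "AMP", "ADP-decoy", "ATP-decoy", "GMP", "GDP", "GTP", "CMP",
  "CDP", "CTP", "UMP", "UDP", "UTP", "IMP", "inosine", "adenosine",
  "guanosine", "cytidine", "uridine", "thymidine", "adenine", "guanine",
  "cytosine", "uracil", "thymine", "hypoxanthine", "xanthine", "urate",
  "nicotinamide", "NAD", "NADH", "NADP", "NADPH", "FAD", "FMN",
  "riboflavin", "thiamine", "pyridoxine", "pyridoxal-phosphate", "biotin",
  "folate", "pantothenate", "coenzyme-A", "acetyl-CoA", "lipoate",
  "glutathione", "spermidine-decoy", "spermine-decoy", "putrescine",
  "agmatine", "GABA", "beta-alanine", "homoserine", "cystathionine",
  "S-adenosyl-methionine", "betaine", "sarcosine", "dimethylglycine",
  "formate", "bicarbonate")

#' Built-in fixture scenarios
#'
#' Named \linkS4class{ScenarioSpec} objects whose ground-truth shifts are
#' the published screening results for four transporters, so that the full
#' pipeline can be validated as a parameter-recovery experiment:
#' \describe{
#'   \item{galp}{\emph{E. coli} galactose transporter GalP, apo midpoint
#'     57.6 degC, sugar library at 50 mM, 5 biological repeats. True
#'     shifts: D-glucosamine 5.7, D-glucose 4.2, D-galactose 2.1 degC,
#'     smaller shifts for three further D-sugars, and zero for the
#'     non-transported L-isoforms.}
#'   \item{mhp1}{sodium-hydantoin symporter Mhp1, apo 51.3 degC,
#'     nucleobase/hydantoin library at 2 mM, 3 repeats. Hydantoin shifts
#'     L-NMH 15.6, L-IMH 14.1, L-BH 13.6, BVH 11.9 degC; nucleobases zero.}
#'   \item{aac}{mitochondrial ADP/ATP carrier, nucleotide library at
#'     2.5 mM, 3 repeats: ATP 7.2, ADP 6.0, dADP 1.8, AMP 0 degC. The apo
#'     midpoint (60 degC) is a synthetic choice; only the shifts are
#'     published.}
#'   \item{tt_pic}{\emph{T. thermophila} mitochondrial phosphate carrier,
#'     apo 56.0 degC, screened against 132 mitochondrial compounds at
#'     pH 6.0: phosphate 4.6, glyoxylate 3.6, acetyl-phosphate 3.2,
#'     phosphoenolpyruvate 2.3 degC; the remaining 128 compounds are
#'     non-binding decoys.}
#'   \item{tt_pic_ph}{the proton-coupled phosphate carrier probed at
#'     pH 6.0 vs pH 8.0: phosphate shifts 4.6 vs 2.6 degC (binding is
#'     proton-assisted); acetyl-phosphate 3.2 vs 1.8 degC (the pH 8
#'     acetyl-phosphate value is a synthetic choice).}
#'   \item{mhp1_ions}{Mhp1 hydantoin shifts under 140 mM NaCl, KCl,
#'     CaCl2 or MgCl2: the published large stabilizations only with the
#'     coupling ion Na+; the small non-coupling-ion shifts (1.0 degC) are
#'     a synthetic choice.}
#' }
#'
#' @return named list of \linkS4class{ScenarioSpec}
#' @examples
#' names(builtinScenarios())
#' builtinScenarios()[["galp"]]
#' @export
builtinScenarios <- function() {
  sugars50 <- function(compounds) ConditionArm(compounds, ph = 8.0,
                                               ions = c(Na = 150),
                                               concMM = 50)
  galp <- ScenarioSpec(
    name = "galp", protein = "GalP",
    apo = UnfoldingParams(tm0 = 57.6),
    arms = list(base = sugars50(list(
      "D-glucosamine" = 5.7, "D-glucose" = 4.2, "D-galactose" = 2.1,
      "D-talose" = 1.5, "2-deoxy-D-glucose" = 1.3,
      "6-deoxy-D-glucose" = 1.0,
      "L-glucosamine" = 0, "L-glucose" = 0, "L-galactose" = 0,
      "L-talose" = 0, "D-arabinose" = 0))),
    nBioReps = 5L)

  mhp1 <- ScenarioSpec(
    name = "mhp1", protein = "Mhp1",
    apo = UnfoldingParams(tm0 = 51.3),
    arms = list(base = ConditionArm(list(
      "L-NMH" = 15.6, "L-IMH" = 14.1, "L-BH" = 13.6, "BVH" = 11.9,
      "adenine" = 0, "guanine" = 0, "cytosine" = 0, "thymine" = 0,
      "uracil" = 0, "hypoxanthine" = 0),
      ph = 7.0, ions = c(Na = 140), concMM = 2)),
    nBioReps = 3L)

  aac <- ScenarioSpec(
    name = "aac", protein = "AAC",
    apo = UnfoldingParams(tm0 = 60.0),
    arms = list(base = ConditionArm(list(
      "ATP" = 7.2, "ADP" = 6.0, "dADP" = 1.8, "AMP" = 0),
      ph = 7.0, ions = c(Na = 50), concMM = 2.5)),
    nBioReps = 3L)

  hits <- list("phosphate" = 4.6, "glyoxylate" = 3.6,
               "acetyl-phosphate" = 3.2, "phosphoenolpyruvate" = 2.3)
  decoys <- setNames(as.list(rep(0, 128)), .MITO_DECOYS[1:128])
  tt_pic <- ScenarioSpec(
    name = "tt_pic", protein = "TtPiC",
    apo = UnfoldingParams(tm0 = 56.0),
    arms = list(base = ConditionArm(c(hits, decoys), ph = 6.0,
                                    ions = c(Na = 50), concMM = 2.5)),
    nBioReps = 3L)

  tt_pic_ph <- ScenarioSpec(
    name = "tt_pic_ph", protein = "TtPiC",
    apo = UnfoldingParams(tm0 = 56.0),
    arms = list(
      ph6 = ConditionArm(list("phosphate" = 4.6, "acetyl-phosphate" = 3.2),
                         ph = 6.0, ions = c(Na = 50), concMM = 2.5),
      ph8 = ConditionArm(list("phosphate" = 2.6, "acetyl-phosphate" = 1.8),
                         ph = 8.0, ions = c(Na = 50), concMM = 2.5)),
    nBioReps = 3L)

  ionArm <- function(ion, big) ConditionArm(
    if (big) list("L-IMH" = 14.1, "L-BH" = 13.6, "BVH" = 11.9)
    else list("L-IMH" = 1.0, "L-BH" = 1.0, "BVH" = 1.0),
    ph = 7.0, ions = setNames(140, ion), concMM = 2)
  mhp1_ions <- ScenarioSpec(
    name = "mhp1_ions", protein = "Mhp1",
    apo = UnfoldingParams(tm0 = 51.3),
    arms = list(Na = ionArm("Na", TRUE), K = ionArm("K", FALSE),
                Ca = ionArm("Ca", FALSE), Mg = ionArm("Mg", FALSE)),
    nBioReps = 3L)

  list(galp = galp, mhp1 = mhp1, aac = aac, tt_pic = tt_pic,
       tt_pic_ph = tt_pic_ph, mhp1_ions = mhp1_ions)
}

.resolveScenario <- function(name) {
  sc <- builtinScenarios()
  if (!name %in% names(sc))
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(sc), collapse = ", ")), call. = FALSE)
  sc[[name]]
}

# --- scenario (de)serialization -------------------------------------------

.armToList <- function(arm) {
  list(ph = arm@ph, ions = as.list(arm@ions), conc_mM = arm@concMM,
       compounds = lapply(arm@compounds, function(x)
         if (is(x, "LigandSpec"))
           list(kd_mM = x@kd, conc_mM = x@conc)
         else x))
}

.armFromList <- function(x) {
  comp <- lapply(x$compounds, function(v)
    if (is.list(v)) NULL else as.numeric(v))
  for (nm in names(x$compounds)) {
    v <- x$compounds[[nm]]
    comp[[nm]] <- if (is.list(v))
      LigandSpec(nm, kd = v$kd_mM, conc = v$conc_mM) else as.numeric(v)
  }
  ions <- unlist(x$ions)
  if (is.null(ions)) ions <- setNames(numeric(0), character(0))
  ConditionArm(comp, ph = x$ph, ions = ions, concMM = x$conc_mM)
}

scenarioToList <- function(spec) {
  list(name = spec@name, protein = spec@protein,
       apo = list(tm0 = spec@apo@tm0, dh_vh = spec@apo@dhVH,
                  a_n = spec@apo@aN, b_n = spec@apo@bN,
                  a_u = spec@apo@aU, b_u = spec@apo@bU,
                  noise_sd = spec@apo@noiseSd),
       arms = lapply(spec@arms, .armToList),
       n_bio_reps = spec@nBioReps, n_tech_controls = spec@nTechControls,
       program = list(t_start = spec@program@tStart,
                      t_end = spec@program@tEnd, step = spec@program@step),
       jitter_sd = spec@jitterSd)
}

scenarioFromList <- function(x) {
  ScenarioSpec(
    name = x$name, protein = x$protein,
    apo = UnfoldingParams(tm0 = x$apo$tm0, dhVH = x$apo$dh_vh,
                          aN = x$apo$a_n, bN = x$apo$b_n, aU = x$apo$a_u,
                          bU = x$apo$b_u, noiseSd = x$apo$noise_sd),
    arms = lapply(x$arms, .armFromList),
    nBioReps = x$n_bio_reps, nTechControls = x$n_tech_controls,
    program = TemperatureProgram(x$program$t_start, x$program$t_end,
                                 x$program$step),
    jitterSd = x$jitter_sd)
}

#' Read or write a scenario specification as YAML
#'
#' @param spec a \linkS4class{ScenarioSpec}
#' @param path YAML file path
#' @return \code{readScenario} returns a \linkS4class{ScenarioSpec};
#'   \code{writeScenario} returns \code{path} invisibly
#' @export
writeScenario <- function(spec, path) {
  yaml::write_yaml(scenarioToList(spec), path)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  scenarioFromList(yaml::read_yaml(path))
}
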