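#' Pathway toggles for the synthetic core network
#'
#' @param phosphoserine_present include the phosphoserine pathway
#'   (3-phosphoglycerate -> phosphohydroxypyruvate -> phosphoserine ->
#'   serine), the putative auxiliary serine supply.
#' @param glyoxylate_shunt_present include isocitrate lyase + malate
#'   synthase.
#' @param tca_variant how the TCA cycle is closed between 2-oxoglutarate and
#'   succinate: `"OGDH"` (conventional 2-oxoglutarate dehydrogenase complex
#'   + succinyl-CoA synthetase), `"bypass"` (2-oxoglutarate decarboxylase +
#'   succinic semialdehyde dehydrogenase), `"GABA"` (glutamate
#'   decarboxylase + GABA transaminase + SSADH), `"glyoxylate"` (close via
#'   the glyoxylate shunt), `"open"` (no closure) or `"all"` (install every
#'   variant simultaneously, for comparison runs).
#' @param include_phk include the phosphoketolase shortcut.
#' @param include_me include the malic enzyme (off by default: flux through
#'   it dissipates energy and is never part of a light-limited optimum).
#' @param include_opp include the oxidative pentose phosphate lump.
#' @return A `core_model_toggles` list.
#' @export
core_model_toggles <- function(phosphoserine_present = TRUE,
                               glyoxylate_shunt_present = FALSE,
                               tca_variant = c("bypass", "OGDH", "GABA",
                                               "glyoxylate", "open", "all"),
                               include_phk = TRUE,
                               include_me = FALSE,
                               include_opp = TRUE) {
  tca_variant <- match.arg(tca_variant)
  structure(list(phosphoserine_present = phosphoserine_present,
                 glyoxylate_shunt_present = glyoxylate_shunt_present,
                 tca_variant = tca_variant,
                 include_phk = include_phk,
                 include_me = include_me,
                 include_opp = include_opp),
            class = "core_model_toggles")
}

# metabolite table for the core network; formulas in Hill notation, neutral
# reference protonation (charge 0); "" marks element-free pseudo-species
# (photons, electron carriers, proton-motive force).
core_metabolites <- function() {
  m <- function(id, formula, name = id, compartment = "c")
    tibble::tibble(id = id, name = name, compartment = compartment,
                   formula = formula, charge = 0L)
  dplyr::bind_rows(
    m("photon_e", "", "photon", "e"), m("photon", ""),
    m("hco3_e", "CHO3", "bicarbonate", "e"), m("hco3", "CHO3", "bicarbonate"),
    m("co2_e", "CO2", "carbon dioxide", "e"), m("co2", "CO2"),
    m("co2f", "CO2", "carboxysomal CO2"),
    m("o2_e", "O2", "oxygen", "e"), m("o2", "O2"),
    m("h2o_e", "H2O", "water", "e"), m("h2o", "H2O"),
    m("h_e", "H", "proton", "e"), m("h", "H"),
    m("no3_e", "HNO3", "nitrate", "e"), m("no3", "HNO3"),
    m("no2", "HNO2", "nitrite"), m("nh4", "H3N", "ammonium"),
    m("so4_e", "H2O4S", "sulfate", "e"), m("so4", "H2O4S"),
    m("h2s", "H2S", "hydrogen sulfide"),
    m("ac_e", "C2H4O2", "acetate", "e"), m("ac", "C2H4O2", "acetate"),
    m("pi_e", "H3O4P", "phosphate", "e"), m("pi", "H3O4P", "phosphate"),
    m("ppi", "H4O7P2", "pyrophosphate"),
    m("atp", "C10H16N5O13P3"), m("adp", "C10H15N5O10P2"),
    m("amp", "C10H14N5O7P"),
    m("nadp", "C21H25N7O17P3"), m("nadph", "C21H26N7O17P3"),
    m("nad", "C21H27N7O14P2"), m("nadh", "C21H28N7O14P2"),
    m("pq", "C53H80O2", "plastoquinone"),
    m("pqh2", "C53H82O2", "plastoquinol"),
    m("pcox", "", "plastocyanin (ox)"), m("pcred", "", "plastocyanin (red)"),
    m("fdox", "", "ferredoxin (ox)"), m("fdred", "", "ferredoxin (red)"),
    m("pmf", "", "proton-motive force"),
    m("o2s", "O2", "superoxide"), m("h2o2", "H2O2", "hydrogen peroxide"),
    m("coa", "C21H36N7O16P3S", "coenzyme A"),
    m("accoa", "C23H38N7O17P3S", "acetyl-CoA"),
    m("succoa", "C25H40N7O19P3S", "succinyl-CoA"),
    m("acp", "C2H5O5P", "acetyl phosphate"),
    m("rubp", "C5H12O11P2", "ribulose 1,5-bisphosphate"),
    m("pg3", "C3H7O7P", "glycerate 3-phosphate"),
    m("pg2", "C3H7O7P", "glycerate 2-phosphate"),
    m("gap", "C3H7O6P", "glyceraldehyde 3-phosphate"),
    m("dhap", "C3H7O6P"), m("fbp", "C6H14O12P2"),
    m("f6p", "C6H13O9P"), m("g6p", "C6H13O9P"), m("g1p", "C6H13O9P"),
    m("x5p", "C5H11O8P"), m("ru5p", "C5H11O8P"), m("r5p", "C5H11O8P"),
    m("s7p", "C7H15O10P"), m("sbp", "C7H16O13P2"), m("e4p", "C4H9O7P"),
    m("pep", "C3H5O6P", "phosphoenolpyruvate"), m("pyr", "C3H4O3", "pyruvate"),
    m("adpglc", "C16H25N5O15P2", "ADP-glucose"),
    m("glycogen", "C6H10O5", "glycogen (glucosyl unit)"),
    m("pglyc", "C2H5O6P", "2-phosphoglycolate"),
    m("glyclt", "C2H4O3", "glycolate"), m("glx", "C2H2O3", "glyoxylate"),
    m("gly", "C2H5NO2", "glycine"), m("ser", "C3H7NO3", "serine"),
    m("cys", "C3H7NO2S", "cysteine"),
    m("hpyr", "C3H4O4", "hydroxypyruvate"),
    m("tsa", "C3H4O4", "tartronate semialdehyde"),
    m("glyc_r", "C3H6O4", "glycerate"),
    m("thf", "C19H23N7O6", "tetrahydrofolate"),
    m("mlthf", "C20H23N7O6", "5,10-methylene-THF"),
    m("php3", "C3H5O7P", "3-phosphohydroxypyruvate"),
    m("pser", "C3H8NO6P", "phosphoserine"),
    m("cit", "C6H8O7", "citrate"), m("icit", "C6H8O7", "isocitrate"),
    m("akg", "C5H6O5", "2-oxoglutarate"),
    m("ssal", "C4H6O3", "succinate semialdehyde"),
    m("succ", "C4H6O4", "succinate"), m("fum", "C4H4O4", "fumarate"),
    m("mal", "C4H6O5", "malate"), m("oaa", "C4H4O5", "oxaloacetate"),
    m("gaba", "C4H9NO2", "4-aminobutanoate"),
    m("glu", "C5H9NO4", "glutamate"), m("gln", "C5H10N2O3", "glutamine"),
    m("ala", "C3H7NO2", "alanine"),
    m("protein", "C3.68H5.56N1O1.9S0.03", "protein equivalent"),
    m("dna", "C10H12N5O6P", "DNA nucleotide equivalent"),
    m("rna", "C10H13N5O7P", "RNA nucleotide equivalent"),
    m("lipid", "C16H32O2", "lipid equivalent"),
    m("pigment", "C49H60N4O5", "pigment equivalent"),
    m("cellwall", "C8H15NO6", "cell-wall equivalent"),
    m("ion", "H5O8PS", "inorganic-ion equivalent"))
}

# reaction list as equation strings; "<->" reversible (-1000,1000),
# "->" irreversible (0,1000); explicit lb/ub override.
# group: "core" always present; otherwise a toggle key.
core_reactions <- function() {
  r <- function(id, eq, category = "metabolic", gpr = "", group = "core",
                lb = NA_real_, ub = NA_real_, name = id)
    tibble::tibble(id = id, eq = eq, category = category, gpr = gpr,
                   group = group, lb = lb, ub = ub, name = name)
  dplyr::bind_rows(
    # exchanges (positive flux = secretion)
    r("EX_photon", "photon_e ->", "exchange", lb = -1000),
    r("EX_hco3", "hco3_e ->", "exchange", lb = -1000),
    r("EX_co2", "co2_e ->", "exchange", lb = 0),
    r("EX_o2", "o2_e ->", "exchange", lb = -1000),
    r("EX_h2o", "h2o_e ->", "exchange", lb = -1000),
    r("EX_h", "h_e ->", "exchange", lb = -1000),
    r("EX_no3", "no3_e ->", "exchange", lb = -1000),
    r("EX_so4", "so4_e ->", "exchange", lb = -1000),
    r("EX_pi", "pi_e ->", "exchange", lb = -1000),
    r("EX_ac", "ac_e ->", "exchange", lb = 0),
    # transport
    r("PHOt", "photon_e -> photon", "transport", "pbpA"),
    r("HCO3t", "hco3_e + pmf -> hco3", "transport", "cmpA and cmpB"),
    r("CO2t", "co2 -> co2_e", "transport"),
    r("O2t", "o2_e <-> o2", "transport"),
    r("H2Ot", "h2o_e <-> h2o", "transport"),
    r("Ht", "h_e <-> h", "transport"),
    r("NO3t", "no3_e + atp + h2o -> no3 + adp + pi", "transport",
      "nrtA and nrtB and nrtC and nrtD"),
    r("SO4t", "so4_e + atp + h2o -> so4 + adp + pi", "transport",
      "cysA and cysT"),
    r("PIt", "pi_e + pmf -> pi", "transport", "pstA and pstB"),
    r("ACt", "ac_e <-> ac", "transport", "actP"),
    # photosynthetic electron transport; pmf is the lumped proton-motive force
    r("PSII", "2 h2o + 2 pq + 4 photon -> o2 + 2 pqh2 + 4 pmf",
      gpr = "psbA and psbB and psbC and psbD", name = "photosystem II"),
    r("B6F", "pqh2 + 2 pcox -> pq + 2 pcred + 4 pmf",
      gpr = "petA and petB and petC", name = "cytochrome b6f"),
    r("PSI", "pcred + fdox + photon -> pcox + fdred",
      gpr = "psaA and psaB and psaC", name = "photosystem I"),
    r("FNR", "2 fdred + nadp + h <-> 2 fdox + nadph", gpr = "petH"),
    r("ATPS", "adp + pi + 4 pmf -> atp + h2o",
      gpr = "atpA and atpB and atpD", name = "ATP synthase"),
    r("PMFL", "pmf ->", "pseudo", name = "proton leak"),
    r("NDH1", "nadph + pq + h -> nadp + pqh2 + 3 pmf",
      gpr = "ndhA and ndhB and ndhC", name = "NDH-1 (NADPH)"),
    r("NDH1N", "nadh + pq + h -> nad + pqh2 + 3 pmf",
      gpr = "ndhA and ndhB and ndhC", group = "ndh1_nadh",
      name = "NDH-1 (NADH)"),
    r("COX", "2 pqh2 + o2 -> 2 pq + 2 h2o + 8 pmf",
      gpr = "ctaC and ctaD and ctaE", name = "terminal oxidase"),
    r("FDP", "2 nadph + o2 -> 2 nadp + 2 h2o", gpr = "flv1 and flv3",
      name = "Mehler-like (flavodiiron)"),
    r("ROS1", "pqh2 + 2 o2 -> pq + 2 o2s + 2 h", name = "PSII superoxide"),
    r("ROS2", "fdred + o2 -> fdox + o2s", name = "PSI Mehler superoxide"),
    r("SOD", "2 o2s + 2 h -> h2o2 + o2", gpr = "sodB"),
    r("PRX", "h2o2 + nadph -> 2 h2o + nadp", gpr = "gpx1 or tpx"),
    r("TH", "nadph + nad <-> nadp + nadh", gpr = "pntA and pntB",
      name = "transhydrogenase"),
    # carbon uptake and fixation; no cytosolic carbonic anhydrase:
    # respired CO2 cannot re-enter the carboxysomal pool
    r("CCM", "hco3 + h -> co2f + h2o", gpr = "ccmK and ccmL and icfA",
      name = "carboxysomal CO2 supply"),
    r("RBC", "rubp + co2f + h2o -> 2 pg3", gpr = "rbcL and rbcS",
      name = "RuBisCO carboxylase"),
    r("RBO", "rubp + o2 -> pg3 + pglyc", gpr = "rbcL and rbcS",
      name = "RuBisCO oxygenase"),
    # Calvin-Benson-Bassham cycle
    r("CBBG", "pg3 + atp + nadph -> gap + adp + pi + nadp",
      gpr = "pgk and gap2", name = "PGK/GAPDH (CBB direction)"),
    r("GLYG", "gap + nad + adp + pi -> pg3 + nadh + atp",
      gpr = "pgk and gap1", name = "GAPDH/PGK (glycolytic direction)"),
    r("TPI", "gap <-> dhap", gpr = "tpiA"),
    r("FBA", "gap + dhap <-> fbp", gpr = "fbaA"),
    r("FBP", "fbp + h2o -> f6p + pi", gpr = "fbpI"),
    r("TKT1", "f6p + gap <-> x5p + e4p", gpr = "tktA"),
    r("SBA", "e4p + dhap <-> sbp", gpr = "fbaA"),
    r("SBP", "sbp + h2o -> s7p + pi", gpr = "fbpI"),
    r("TKT2", "s7p + gap <-> x5p + r5p", gpr = "tktA"),
    r("TAL", "s7p + gap <-> e4p + f6p", gpr = "talB",
      name = "transaldolase"),
    r("RPE", "x5p <-> ru5p", gpr = "rpe"),
    r("RPI", "r5p <-> ru5p", gpr = "rpiA"),
    r("PRK", "ru5p + atp -> rubp + adp", gpr = "prkB"),
    r("PGI", "f6p <-> g6p", gpr = "pgi"),
    r("GPM", "g6p <-> g1p", gpr = "pgm", name = "phosphoglucomutase"),
    # glycogen
    r("ADPGS", "g1p + atp -> adpglc + ppi", gpr = "glgC"),
    r("GLGS", "adpglc -> glycogen + adp", gpr = "glgA",
      name = "glycogen synthase"),
    r("GLGP", "glycogen + pi -> g1p", gpr = "glgP",
      name = "glycogen phosphorylase"),
    r("PPA", "ppi + h2o -> 2 pi", gpr = "ppa"),
    r("DM_glycogen", "glycogen ->", "pseudo", lb = 0,
      name = "glycogen storage sink"),
    r("SRC_glycogen", "-> glycogen", "pseudo", lb = 0, ub = 0,
      name = "glycogen storage source"),
    # lower glycolysis and acetyl-CoA
    r("PGAM", "pg3 <-> pg2", gpr = "gpmB", name = "phosphoglycerate mutase"),
    r("ENO", "pg2 <-> pep + h2o", gpr = "eno"),
    r("PYK", "pep + adp -> pyr + atp", gpr = "pyk1"),
    r("PFK", "f6p + atp -> fbp + adp", gpr = "pfkA"),
    r("PDH", "pyr + coa + nad -> accoa + co2 + nadh",
      gpr = "pdhA and pdhB and pdhC", name = "pyruvate dehydrogenase"),
    r("PHK1", "f6p + pi -> acp + e4p + h2o", gpr = "xfp", group = "phk",
      name = "phosphoketolase (F6P)"),
    r("PHK2", "x5p + pi -> acp + gap + h2o", gpr = "xfp", group = "phk",
      name = "phosphoketolase (X5P)"),
    r("PTA", "acp + coa <-> accoa + pi", gpr = "pta"),
    r("ACK", "acp + adp <-> ac + atp", gpr = "ackA"),
    r("ACS", "ac + atp + coa -> accoa + amp + ppi", gpr = "acsA"),
    r("ADK", "atp + amp <-> 2 adp", gpr = "adk"),
    # oxidative pentose phosphate lump (G6PDH + lactonase + 6PGDH)
    r("ZWF", "g6p + 2 nadp + h2o -> ru5p + co2 + 2 nadph",
      gpr = "zwf and gnd", group = "opp", name = "OPP pathway (lump)"),
    # photorespiratory salvage
    r("PGP", "pglyc + h2o -> glyclt + pi", gpr = "pgp",
      name = "phosphoglycolate phosphatase"),
    r("GLCDH", "glyclt + pq -> glx + pqh2", gpr = "glcD",
      name = "glycolate dehydrogenase"),
    r("GGAT", "glx + glu -> gly + akg", gpr = "ggt",
      name = "glyoxylate aminotransferase"),
    r("SGAT", "glx + ser -> gly + hpyr", gpr = "sgt",
      name = "serine-glyoxylate aminotransferase"),
    r("HPR", "hpyr + nadph -> glyc_r + nadp", gpr = "hprA",
      name = "hydroxypyruvate reductase"),
    r("GCL", "2 glx -> tsa + co2", gpr = "gcl",
      name = "glyoxylate carboligase"),
    r("TSR", "tsa + nadph -> glyc_r + nadp", gpr = "tsr"),
    r("HPYRT", "hpyr <-> tsa", "spontaneous",
      name = "hydroxypyruvate tautomerisation"),
    r("GLYK", "glyc_r + atp -> pg3 + adp", gpr = "glxK",
      name = "glycerate kinase"),
    # serine / glycine / C1
    r("PGCD", "pg3 + nadp -> php3 + nadph", gpr = "serA",
      group = "phosphoserine", name = "phosphoglycerate dehydrogenase"),
    r("PSAT", "php3 + glu -> pser + akg", gpr = "serC",
      group = "phosphoserine", name = "phosphoserine transaminase"),
    r("PSP", "pser + h2o -> ser + pi", gpr = "serB",
      group = "phosphoserine", name = "phosphoserine phosphatase"),
    r("SHMT", "ser + thf <-> gly + mlthf + h2o", gpr = "glyA",
      name = "serine hydroxymethyltransferase"),
    r("GCS", "gly + thf + nadp <-> mlthf + co2 + nh4 + nadph",
      gpr = "gcvP and gcvT and gcvH", name = "glycine cleavage system"),
    r("CYSS", "ser + h2s -> cys + h2o", gpr = "cysK",
      name = "cysteine synthesis (lump)"),
    # TCA cycle and closure variants
    r("CS", "accoa + oaa + h2o -> cit + coa", gpr = "gltA",
      name = "citrate synthase"),
    r("ACO", "cit <-> icit", gpr = "acnB", name = "aconitase"),
    r("ICD", "icit + nadp -> akg + co2 + nadph", gpr = "icd",
      name = "isocitrate dehydrogenase"),
    r("OGDH", "akg + coa + nad -> succoa + co2 + nadh",
      gpr = "sucA and sucB and lpd", group = "ogdh",
      name = "2-oxoglutarate dehydrogenase complex"),
    r("SCS", "succoa + adp + pi <-> succ + coa + atp",
      gpr = "sucC and sucD", group = "ogdh",
      name = "succinyl-CoA synthetase"),
    r("OGDC", "akg -> ssal + co2", gpr = "sll1981", group = "bypass",
      name = "2-oxoglutarate decarboxylase"),
    r("SSADH", "ssal + nadp + h2o -> succ + nadph", gpr = "slr0370",
      group = "ssadh", name = "succinic semialdehyde dehydrogenase"),
    r("GAD", "glu -> gaba + co2", gpr = "gadB", group = "gaba",
      name = "glutamate decarboxylase"),
    r("GABAT", "gaba + akg -> ssal + glu", gpr = "gabT", group = "gaba",
      name = "GABA transaminase"),
    r("ICL", "icit -> glx + succ", gpr = "aceA", group = "glyoxylate_shunt",
      name = "isocitrate lyase"),
    r("MALS", "accoa + glx + h2o -> mal + coa", gpr = "aceB",
      group = "glyoxylate_shunt", name = "malate synthase"),
    r("SDH", "succ + pq -> fum + pqh2", gpr = "sdhA and sdhB",
      name = "succinate dehydrogenase"),
    r("FUM", "fum + h2o <-> mal", gpr = "fumC", name = "fumarase"),
    r("MDH", "mal + nad <-> oaa + nadh", gpr = "mdh",
      name = "malate dehydrogenase"),
    r("ME", "mal + nadp -> pyr + co2 + nadph", gpr = "me1", group = "me",
      name = "malic enzyme"),
    r("PEPC", "pep + hco3 -> oaa + pi", gpr = "ppc",
      name = "PEP carboxylase"),
    r("PEPCK", "oaa + atp -> pep + co2 + adp", gpr = "pckA",
      name = "PEP carboxykinase"),
    # nitrogen and sulfur assimilation
    r("NR", "no3 + 2 fdred + 2 h -> no2 + 2 fdox + h2o", gpr = "narB",
      name = "nitrate reductase"),
    r("NIR", "no2 + 6 fdred + 7 h -> nh4 + 6 fdox + 2 h2o", gpr = "nirA",
      name = "nitrite reductase"),
    r("GS", "glu + nh4 + atp -> gln + adp + pi", gpr = "glnA",
      name = "glutamine synthetase"),
    r("GOGAT", "gln + akg + 2 fdred + 2 h -> 2 glu + 2 fdox", gpr = "glsF",
      name = "glutamate synthase"),
    r("GDH", "glu + nadp + h2o -> akg + nh4 + nadph", gpr = "gdhA",
      name = "glutamate dehydrogenase"),
    r("SAS", "so4 + atp + 4 nadph -> h2s + amp + ppi + 3 h2o + 4 nadp",
      gpr = "cysD and cysH and sir", name = "sulfate assimilation (lump)"),
    r("ALATA", "pyr + glu <-> ala + akg", gpr = "alaT",
      name = "alanine transaminase"),
    # biomass component synthesis (lumped, balanced)
    r("PROTS", paste("0.4 glu + 0.35 ala + 0.12 gly + 0.1 ser + 0.03 cys",
                     "+ 4.3 atp + 3.3 h2o -> protein + 4.3 adp + 4.3 pi"),
      gpr = "rpsA and rplB", name = "protein synthesis (lump)"),
    r("DNAS", "r5p + gly + 3 co2 + 4 nh4 + 6 atp + 4 nadph -> dna + 4 h2o + 6 adp + 6 pi + 4 nadp",
      gpr = "purF and pyrB and dnaE", name = "DNA synthesis (lump)"),
    r("RNAS", "r5p + gly + 3 co2 + 4 nh4 + 6 atp + 4 nadph -> rna + 3 h2o + 6 adp + 6 pi + 4 nadp",
      gpr = "purF and pyrB and rpoA", name = "RNA synthesis (lump)"),
    r("LIPS", "8 accoa + 7 atp + 14 nadph + h2o -> lipid + 8 coa + 7 adp + 7 pi + 14 nadp",
      gpr = "accA and fabD and fabH", name = "lipid synthesis (lump)"),
    r("PIGS", "8 glu + 3 pyr + 6 atp + 12 nadph -> pigment + 4 nh4 + 30 h2o + 6 adp + 6 pi + 12 nadp",
      gpr = "hemA and chlH and chlP", name = "pigment synthesis (lump)"),
    r("CWS", "f6p + nh4 + accoa + atp + h2o -> cellwall + coa + adp + 2 pi",
      gpr = "glmS and murA", name = "cell-wall synthesis (lump)"),
    r("IONS", "pi + so4 -> ion", gpr = "pstS",
      name = "ion assimilation (lump)"),
    # demand reactions for the diurnal objective
    r("DM_protein", "protein ->", "pseudo", lb = 0),
    r("DM_dna", "dna ->", "pseudo", lb = 0),
    r("DM_rna", "rna ->", "pseudo", lb = 0),
    r("DM_lipid", "lipid ->", "pseudo", lb = 0),
    r("DM_pigment", "pigment ->", "pseudo", lb = 0),
    r("DM_cellwall", "cellwall ->", "pseudo", lb = 0),
    r("DM_ion", "ion ->", "pseudo", lb = 0),
    # maintenance and growth
    r("NGAM", "atp + h2o -> adp + pi", "pseudo", lb = 0,
      name = "maintenance ATPase"),
    r("BOF", paste("5 protein + 0.09 dna + 0.44 rna + 0.39 lipid",
                   "+ 0.073 pigment + 0.36 cellwall + 0.19 ion + 30 atp",
                   "+ 30 h2o -> 30 adp + 30 pi"),
      "biomass", name = "biomass objective function"))
}

# parse "2 a + b -> c" into stoichiometry rows; returns list(sto, reversible)
parse_equation <- function(id, eq) {
  rev <- grepl("<->", eq, fixed = TRUE)
  sides <- strsplit(eq, "<->|->")[[1]]
  lhs <- trimws(sides[1])
  rhs <- if (length(sides) > 1) trimws(sides[2]) else ""
  parse_side <- function(side, sign) {
    if (side == "") return(NULL)
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(tm) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 2) {
        tibble::tibble(reaction = id, metabolite = parts[2],
                       coefficient = sign * as.numeric(parts[1]))
      } else {
        tibble::tibble(reaction = id, metabolite = parts[1],
                       coefficient = sign)
      }
    })
    dplyr::bind_rows(out)
  }
  sto <- dplyr::bind_rows(parse_side(lhs, -1), parse_side(rhs, +1))
  # merge duplicated metabolites (none expected, but be safe)
  sto <- dplyr::summarise(dplyr::group_by(sto, .data$reaction, .data$metabolite),
                          coefficient = sum(.data$coefficient), .groups = "drop")
  sto <- sto[sto$coefficient != 0, ]
  list(sto = sto, reversible = rev)
}

# which reaction groups a toggle set activates
active_groups <- function(toggles) {
  g <- "core"
  variant_groups <- switch(toggles$tca_variant,
    OGDH = "ogdh",
    bypass = c("bypass", "ssadh"),
    GABA = c("gaba", "ssadh"),
    glyoxylate = "glyoxylate_shunt",
    open = character(0),
    all = c("ogdh", "bypass", "gaba", "ssadh", "glyoxylate_shunt"))
  g <- c(g, variant_groups, "ndh1_nadh") # NDH-1 NADH use is bound-toggled later
  if (toggles$phosphoserine_present) g <- c(g, "phosphoserine")
  if (toggles$glyoxylate_shunt_present) g <- c(g, "glyoxylate_shunt")
  if (toggles$include_phk) g <- c(g, "phk")
  if (toggles$include_me) g <- c(g, "me")
  if (toggles$include_opp) g <- c(g, "opp")
  unique(g)
}

#' Build the synthetic cyanobacterial core network
#'
#' Generates a mass-balanced core model of cyanobacterial phototrophic
#' metabolism (on the order of a hundred reactions): photosynthetic electron
#' transport with explicit photon and proton-motive-force pseudo-species,
#' the CBB cycle with separate RuBisCO carboxylase and oxygenase, the
#' photorespiratory salvage network with both the glycine and the glycerate
#' route, an optional phosphoserine branch, lower glycolysis, optional
#' phosphoketolase / OPP / malic enzyme, a TCA cycle with four closure
#' options, glycogen storage, nitrate and sulfate assimilation, Mehler-like
#' and superoxide-producing oxygen reactions with a SOD/peroxidase
#' detoxification route, maintenance ATPase, and a biomass objective over
#' lumped protein / DNA / RNA / lipid / pigment / cell-wall / ion
#' components.
#'
#' Respired cytosolic CO2 cannot re-enter the carboxysomal fixation pool
#' (there is no cytosolic carbonic anhydrase), so net carbon enters only as
#' bicarbonate; this mirrors the one-way carbon-concentrating mechanism of
#' cyanobacteria.
#'
#' The model passes [check_balance()] for C, N, O, P, S and charge, and
#' sustains positive biomass flux under the phototrophic reference
#' configuration. Reaction roles (which id is "PSII", "oxygenase", ...) are
#' attached as the `roles` attribute; see [core_model_roles()].
#'
#' @param toggles a [core_model_toggles()] configuration.
#' @return A `metabolic_model` with a `roles` attribute and a `manifest`
#'   attribute (category counts as generated).
#' @export
#' @examples
#' m <- build_core_model()
#' nrow(check_balance(m)) # 0
build_core_model <- function(toggles = core_model_toggles()) {
  rxn_def <- core_reactions()
  rxn_def <- rxn_def[rxn_def$group %in% active_groups(toggles), ]
  rxn_def <- rxn_def[!duplicated(rxn_def$id), ]
  parsed <- lapply(seq_len(nrow(rxn_def)),
                   function(i) parse_equation(rxn_def$id[i], rxn_def$eq[i]))
  sto <- dplyr::bind_rows(lapply(parsed, `[[`, "sto"))
  rev <- vapply(parsed, `[[`, logical(1), "reversible")
  lb <- ifelse(is.na(rxn_def$lb), ifelse(rev, -1000, 0), rxn_def$lb)
  ub <- ifelse(is.na(rxn_def$ub), 1000, rxn_def$ub)
  rxn <- tibble::tibble(id = rxn_def$id, name = rxn_def$name,
                        lower_bound = lb, upper_bound = ub,
                        gene_association = rxn_def$gpr,
                        category = rxn_def$category)
  met <- core_metabolites()
  met <- met[met$id %in% unique(sto$metabolite), ]
  comp <- tibble::tibble(id = c("c", "e"),
                         name = c("cytosol", "extracellular"))
  model <- metabolic_model(comp, met, rxn, sto, objective_id = "BOF",
                           id = "cyano_core")
  attr(model, "roles") <- core_roles_table(model)
  attr(model, "toggles") <- toggles
  attr(model, "manifest") <- table(rxn$category)
  model
}

core_roles_all <- c(
  photon_uptake = "PHOt", psii = "PSII", psi = "PSI",
  terminal_oxidase = "COX", mehler_like = "FDP",
  ros_psii = "ROS1", ros_psi = "ROS2",
  carboxylase = "RBC", oxygenase = "RBO",
  biomass = "BOF", maintenance = "NGAM",
  glycogen_sink = "DM_glycogen", glycogen_source = "SRC_glycogen",
  glycogen_synthase = "GLGS", glycogen_phosphorylase = "GLGP",
  glucomutase = "GPM",
  bicarbonate_exchange = "EX_hco3", acetate_exchange = "EX_ac",
  co2_exchange = "EX_co2", o2_exchange = "EX_o2",
  photon_exchange = "EX_photon",
  transhydrogenase = "TH", ndh1_nadph = "NDH1", ndh1_nadh = "NDH1N",
  opp = "ZWF", pgk_cbb = "CBBG", pgam = "PGAM",
  ogdh = "OGDH", scs = "SCS", ogdc = "OGDC", ssadh = "SSADH",
  gad = "GAD", gabat = "GABAT", icl = "ICL", mals = "MALS",
  citrate_synthase = "CS", aconitase = "ACO", icd = "ICD",
  sdh = "SDH", fumarase = "FUM", mdh = "MDH",
  glyoxylate_to_glycine = "GGAT", glyoxylate_to_glycerate = "GCL",
  phosphoketolase = "PHK1", phosphoketolase_x5p = "PHK2",
  pdh = "PDH", gdh = "GDH")

core_roles_table <- function(model) {
  core_roles_all[core_roles_all %in% model$reactions$id]
}

#' Reaction-role mapping of a model
#'
#' The scenario suite addresses reactions by functional role (`"psii"`,
#' `"oxygenase"`, `"terminal_oxidase"`, ...) rather than by id, so any model
#' exposing the same roles can be analysed. For models built by
#' [build_core_model()] the mapping ships with the model; for third-party
#' models supply a named character vector `role -> reaction id` via the
#' `roles` argument of the scenario functions or set it with
#' `set_model_roles()`.
#'
#' @param model a `metabolic_model`.
#' @return Named character vector mapping role names to reaction ids.
#' @export
core_model_roles <- function(model) {
  r <- attr(model, "roles")
  if (is.null(r)) stop("model carries no role mapping; use set_model_roles()")
  r
}

#' @rdname core_model_roles
#' @param roles named character vector `role -> reaction id`.
#' @export
set_model_roles <- function(model, roles) {
  missing <- setdiff(roles, model$reactions$id)
  if (length(missing))
    stop("role mapping names unknown reaction: ", missing[1])
  attr(model, "roles") <- roles
  model
}

#' Small LP fixtures with known optima
#'
#' Tiny flux models (at most 8 reactions) whose optimum and flux-variability
#' ranges are known in closed form, used to validate the LP engine against
#' exhaustive vertex enumeration.
#'
#' @param name one of `"chain"`, `"branch"`, `"parallel"`,
#'   `"wasteful_cycle"`.
#' @return A list with elements `model`, `optimum` (known objective value)
#'   and `fva` (tibble `reaction`, `min`, `max` at objective fraction 1).
#' @export
make_lp_fixture <- function(name = c("chain", "branch", "parallel",
                                     "wasteful_cycle")) {
  name <- match.arg(name)
  comp <- tibble::tibble(id = "c", name = "cytosol")
  build <- function(mets, rxn, sto, obj) {
    met <- tibble::tibble(id = mets, name = mets, compartment = "c",
                          formula = NA_character_, charge = NA_integer_)
    metabolic_model(comp, met, rxn, sto, objective_id = obj, id = name)
  }
  tib <- tibble::tibble
  switch(name,
    chain = {
      rxn <- tib(id = c("SRC_A", "R1", "BIO"),
                 lower_bound = 0, upper_bound = c(10, 1000, 1000),
                 category = c("exchange", "metabolic", "biomass"))
      sto <- tib(reaction = c("SRC_A", "R1", "R1", "BIO"),
                 metabolite = c("A", "A", "B", "B"),
                 coefficient = c(1, -1, 1, -1))
      list(model = build(c("A", "B"), rxn, sto, "BIO"), optimum = 10,
           fva = tib(reaction = c("SRC_A", "R1", "BIO"), min = 10, max = 10))
    },
    branch = {
      # high-yield route A -> B, low-yield route 2A -> B
      rxn <- tib(id = c("SRC_A", "R_hi", "R_lo", "BIO"),
                 lower_bound = 0, upper_bound = c(10, 1000, 1000, 1000),
                 category = c("exchange", "metabolic", "metabolic", "biomass"))
      sto <- tib(reaction = c("SRC_A", "R_hi", "R_hi", "R_lo", "R_lo", "BIO"),
                 metabolite = c("A", "A", "B", "A", "B", "B"),
                 coefficient = c(1, -1, 1, -2, 1, -1))
      list(model = build(c("A", "B"), rxn, sto, "BIO"), optimum = 10,
           fva = tib(reaction = c("SRC_A", "R_hi", "R_lo", "BIO"),
                     min = c(10, 10, 0, 10), max = c(10, 10, 0, 10)))
    },
    parallel = {
      rxn <- tib(id = c("SRC_A", "P1", "P2", "BIO"),
                 lower_bound = 0, upper_bound = c(10, 10, 10, 1000),
                 category = c("exchange", "metabolic", "metabolic", "biomass"))
      sto <- tib(reaction = c("SRC_A", "P1", "P1", "P2", "P2", "BIO"),
                 metabolite = c("A", "A", "B", "A", "B", "B"),
                 coefficient = c(1, -1, 1, -1, 1, -1))
      list(model = build(c("A", "B"), rxn, sto, "BIO"), optimum = 10,
           fva = tib(reaction = c("SRC_A", "P1", "P2", "BIO"),
                     min = c(10, 0, 0, 10), max = c(10, 10, 10, 10)))
    },
    wasteful_cycle = {
      # BIO needs A and energy E; GEN_E burns A; CYC wastes E
      rxn <- tib(id = c("SRC_A", "GEN_E", "CYC", "BIO"),
                 lower_bound = 0, upper_bound = c(10, 1000, 1000, 1000),
                 category = c("exchange", "metabolic", "pseudo", "biomass"))
      sto <- tib(reaction = c("SRC_A", "GEN_E", "GEN_E", "CYC",
                              "BIO", "BIO"),
                 metabolite = c("A", "A", "E", "E", "A", "E"),
                 coefficient = c(1, -1, 2, -1, -1, -1))
      list(model = build(c("A", "E"), rxn, sto, "BIO"), optimum = 20 / 3,
           fva = tib(reaction = c("SRC_A", "GEN_E", "CYC", "BIO"),
                     min = c(10, 10 / 3, 0, 20 / 3),
                     max = c(10, 10 / 3, 0, 20 / 3)))
    })
}
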