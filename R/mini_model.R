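# Deterministic synthetic "mini" metabolic network.
#
# A compact, fully element- and charge-balanced fungal network carrying the
# pathway topology relevant to stilbene production: glucose/sucrose/
# rhamnose/ethanol uptake, glycolysis (with PFK) and gluconeogenesis, the
# oxidative/non-oxidative pentose phosphate pathway producing e4p, the
# complete shikimate chain (3ddah7p -> dqt -> dhsk -> sme -> sme3p ->
# 3psme -> chor) to prephenate, tyrosine and phenylalanine, the
# phenylpropanoid route (PTAL, C4H, 4CL), malonyl-CoA synthesis (ACC), a
# CHS carrying stilbene-synthase activity (3 malonyl-CoA + p-coumaroyl-CoA
# -> resveratrol) next to a naringenin-chalcone branch from the same
# substrates, resveratrol O-methylation (pterostilbene) and hydroxylation
# (piceatannol) side branches, the ethanol assimilation route
# (etoh -> acald -> ac -> acetyl-CoA, with the acetate-activating step
# written exactly as `ac[c] + coa[c] + atp[c] -> h[c] + accoa[c] + ppi[c]
# + amp[c]` under the id g0770), a fatty-acid (malonyl-CoA) drain, a TCA
# sketch supplying 2-oxoglutarate -> glutamate, lumped respiration and a
# biomass reaction assembled by the biomass module.
#
# All numbers (formulas, bounds) are fixed by construction; the default
# build is bit-reproducible and takes no random input. Diphosphate is
# modeled fully deprotonated (P2O7^4-), the convention under which the
# g0770 acetate-activation string balances exactly as written.

mini_metabolites <- function() {
  def <- function(base, name, formula, charge, comps = "c") {
    tibble::tibble(base = base, name = name, formula = formula,
                   charge = as.integer(charge), comp = list(comps))
  }
  d <- dplyr::bind_rows(
    def("glc__D", "D-glucose", "C6H12O6", 0, c("c", "e")),
    def("fru", "D-fructose", "C6H12O6", 0),
    def("sucr", "sucrose", "C12H22O11", 0, c("c", "e")),
    def("rmn", "L-rhamnose", "C6H12O5", 0, c("c", "e")),
    def("rmnl", "L-rhamnono-1,4-lactone", "C6H10O5", 0),
    def("rmnt", "L-rhamnonate", "C6H11O6", -1),
    def("etoh", "ethanol", "C2H6O", 0, c("c", "e")),
    def("acald", "acetaldehyde", "C2H4O", 0),
    def("ac", "acetate", "C2H3O2", -1),
    def("g6p", "D-glucose 6-phosphate", "C6H11O9P", -2),
    def("f6p", "D-fructose 6-phosphate", "C6H11O9P", -2),
    def("fdp", "D-fructose 1,6-bisphosphate", "C6H10O12P2", -4),
    def("g3p", "glyceraldehyde 3-phosphate", "C3H5O6P", -2),
    def("3pg", "3-phospho-D-glycerate", "C3H4O7P", -3),
    def("pep", "phosphoenolpyruvate", "C3H2O6P", -3),
    def("pyr", "pyruvate", "C3H3O3", -1),
    def("ru5p__D", "D-ribulose 5-phosphate", "C5H9O8P", -2),
    def("r5p", "D-ribose 5-phosphate", "C5H9O8P", -2),
    def("xu5p__D", "D-xylulose 5-phosphate", "C5H9O8P", -2),
    def("s7p", "sedoheptulose 7-phosphate", "C7H13O10P", -2),
    def("e4p", "D-erythrose 4-phosphate", "C4H7O7P", -2),
    def("atp", "ATP", "C10H12N5O13P3", -4),
    def("adp", "ADP", "C10H12N5O10P2", -3),
    def("amp", "AMP", "C10H12N5O7P", -2),
    def("pi", "phosphate", "HO4P", -2, c("c", "e")),
    def("ppi", "diphosphate", "O7P2", -4),
    def("h", "H+", "H", 1, c("c", "e")),
    def("h2o", "water", "H2O", 0, c("c", "e")),
    def("co2", "CO2", "CO2", 0, c("c", "e")),
    def("o2", "O2", "O2", 0, c("c", "e")),
    def("nh4", "ammonium", "H4N", 1, c("c", "e")),
    def("h2s", "hydrogen sulfide", "H2S", 0),
    def("so3", "sulfite", "O3S", -2, c("c", "e")),
    def("nad", "NAD+", "C21H26N7O14P2", -1),
    def("nadh", "NADH", "C21H27N7O14P2", -2),
    def("nadp", "NADP+", "C21H25N7O17P3", -3),
    def("nadph", "NADPH", "C21H26N7O17P3", -4),
    def("coa", "coenzyme A", "C21H32N7O16P3S", -4),
    def("accoa", "acetyl-CoA", "C23H34N7O17P3S", -4),
    def("malcoa", "malonyl-CoA", "C24H33N7O19P3S", -5),
    def("oaa", "oxaloacetate", "C4H2O5", -2),
    def("cit", "citrate", "C6H5O7", -3),
    def("icit", "isocitrate", "C6H5O7", -3),
    def("akg", "2-oxoglutarate", "C5H4O5", -2),
    def("glu__L", "L-glutamate", "C5H8NO4", -1),
    def("ala__L", "L-alanine", "C3H7NO2", 0),
    def("ser__L", "L-serine", "C3H7NO3", 0),
    def("cys__L", "L-cysteine", "C3H7NO2S", 0),
    def("phe__L", "L-phenylalanine", "C9H11NO2", 0, c("c", "e")),
    def("tyr__L", "L-tyrosine", "C9H11NO3", 0, c("c", "e")),
    def("3ddah7p", "2-dehydro-3-deoxy-D-arabino-heptonate 7-phosphate",
        "C7H10O10P", -3),
    def("dqt", "3-dehydroquinate", "C7H9O6", -1),
    def("dhsk", "3-dehydroshikimate", "C7H7O5", -1),
    def("sme", "shikimate", "C7H9O5", -1),
    def("sme3p", "shikimate 3-phosphate", "C7H8O8P", -3),
    def("3psme", "5-O-(1-carboxyvinyl)-3-phosphoshikimate", "C10H9O10P", -4),
    def("chor", "chorismate", "C10H8O6", -2),
    def("pphn", "prephenate", "C10H8O6", -2),
    def("34hpp", "4-hydroxyphenylpyruvate", "C9H7O4", -1),
    def("phpyr", "phenylpyruvate", "C9H7O3", -1),
    def("couma", "4-coumarate", "C9H7O3", -1),
    def("cinnm", "trans-cinnamate", "C9H7O2", -1),
    def("4cmcoa", "p-coumaroyl-CoA", "C30H38N7O18P3S", -4),
    def("resv", "trans-resveratrol", "C14H12O3", 0, c("c", "e")),
    def("ptsb", "pterostilbene", "C16H16O3", 0, c("c", "e")),
    def("pice", "piceatannol", "C14H12O4", 0, c("c", "e")),
    def("naring", "naringenin chalcone", "C15H12O5", 0),
    def("amet", "S-adenosyl-L-methionine", "C15H23N6O5S", 1),
    def("ahcys", "S-adenosyl-L-homocysteine", "C14H20N6O5S", 0),
    def("mnl", "D-mannitol", "C6H14O6", 0),
    def("glucan", "beta-glucan unit", "C6H10O5", 0),
    def("hdca", "palmitate", "C16H31O2", -1),
    def("ash", "ash (non-elemental pseudo-species)", "", NA),
    def("damp", "dAMP", "C10H12N5O6P", -2),
    def("dtmp", "dTMP", "C10H13N2O8P", -2),
    def("dgmp", "dGMP", "C10H12N5O7P", -2),
    def("dcmp", "dCMP", "C9H12N3O7P", -2)
  )
  rows <- lapply(seq_len(nrow(d)), function(i) {
    comps <- d$comp[[i]]
    metabolite_tbl(
      id = paste0(d$base[i], "[", comps, "]"),
      name = d$name[i], formula = d$formula[i], charge = d$charge[i],
      compartment = comps
    )
  })
  dplyr::bind_rows(rows)
}

mini_reactions <- function() {
  R <- function(id, eq, lb = 0, ub = 1000, gpr = "", sub = "",
                kind = "metabolic", name = id) {
    reaction_tbl(id = id, stoichiometry = list(parse_reaction_equation(eq)),
                 name = name, lb = lb, ub = ub, gpr = gpr, subsystem = sub,
                 kind = kind)
  }
  ex <- function(base, lb = 0) {
    R(paste0("EX_", base, "_e"), paste0(base, "[e] ->"), lb = lb,
      kind = "exchange", sub = "exchange", name = paste(base, "exchange"))
  }
  dplyr::bind_rows(
    # --- exchanges (closed uptake by default; opened via set_medium) ---
    ex("glc__D"), ex("sucr"), ex("rmn"), ex("etoh"), ex("resv"), ex("ptsb"),
    ex("pice"), ex("co2"), ex("o2"), ex("nh4"), ex("pi"), ex("so3"),
    ex("h2o"), ex("h"), ex("phe__L"), ex("tyr__L"),
    # --- transporters ---
    R("GLCt", "glc__D[e] -> glc__D[c]", gpr = "HXT1", kind = "transport",
      sub = "transport"),
    R("SUCRt", "sucr[e] -> sucr[c]", gpr = "SUT1", kind = "transport",
      sub = "transport"),
    R("RMNt", "rmn[e] -> rmn[c]", gpr = "RHT1", kind = "transport",
      sub = "transport"),
    R("ETOHt", "etoh[e] <=> etoh[c]", lb = -1000, kind = "transport",
      sub = "transport"),
    R("RESVt", "resv[c] -> resv[e]", gpr = "ABC1 or ABC2",
      kind = "transport", sub = "transport"),
    R("PTSBt", "ptsb[c] -> ptsb[e]", kind = "transport", sub = "transport"),
    R("PICEt", "pice[c] -> pice[e]", kind = "transport", sub = "transport"),
    R("CO2t", "co2[c] <=> co2[e]", lb = -1000, kind = "transport",
      sub = "transport"),
    R("O2t", "o2[e] <=> o2[c]", lb = -1000, kind = "transport",
      sub = "transport"),
    R("H2Ot", "h2o[e] <=> h2o[c]", lb = -1000, kind = "transport",
      sub = "transport"),
    R("Ht", "h[e] <=> h[c]", lb = -1000, kind = "spontaneous",
      sub = "transport"),
    R("NH4t", "nh4[e] -> nh4[c]", gpr = "MEP1", kind = "transport",
      sub = "transport"),
    R("PIt", "pi[e] -> pi[c]", gpr = "PHO84", kind = "transport",
      sub = "transport"),
    R("SO3t", "so3[e] -> so3[c]", gpr = "SUL1", kind = "transport",
      sub = "transport"),
    R("PHEt", "phe__L[e] -> phe__L[c]", gpr = "AAP1", kind = "transport",
      sub = "transport"),
    R("TYRt", "tyr__L[e] -> tyr__L[c]", gpr = "AAP1", kind = "transport",
      sub = "transport"),
    # --- sucrose utilization ---
    R("INV", "sucr[c] + h2o[c] -> glc__D[c] + fru[c]", gpr = "INV1",
      sub = "sucrose"),
    R("HEXf", "fru[c] + atp[c] -> f6p[c] + adp[c] + h[c]",
      gpr = "HXK1 or HXK2", sub = "sucrose"),
    # --- glycolysis / gluconeogenesis ---
    R("HEX1", "glc__D[c] + atp[c] -> g6p[c] + adp[c] + h[c]",
      gpr = "HXK1 or HXK2", sub = "glycolysis"),
    R("PGI", "g6p[c] <=> f6p[c]", lb = -1000, gpr = "PGI1",
      sub = "glycolysis"),
    R("PFK", "f6p[c] + atp[c] -> fdp[c] + adp[c] + h[c]", gpr = "PFK",
      sub = "glycolysis"),
    R("FBA2", "fdp[c] <=> 2 g3p[c]", lb = -1000, gpr = "FBA1",
      sub = "glycolysis", name = "aldolase + triose isomerase (lumped)"),
    R("FBP", "fdp[c] + h2o[c] -> f6p[c] + pi[c]", gpr = "FBP1",
      sub = "gluconeogenesis"),
    R("GAPDPGK",
      "g3p[c] + nad[c] + pi[c] + adp[c] <=> 3pg[c] + atp[c] + nadh[c] + h[c]",
      lb = -1000, gpr = "TDH1 and PGK1", sub = "glycolysis",
      name = "GAPDH + phosphoglycerate kinase (lumped)"),
    R("ENO", "3pg[c] <=> pep[c] + h2o[c]", lb = -1000, gpr = "ENO1",
      sub = "glycolysis"),
    R("PYK", "pep[c] + adp[c] + h[c] -> pyr[c] + atp[c]", gpr = "PYK1",
      sub = "glycolysis"),
    R("PPS", "pyr[c] + atp[c] + h2o[c] -> pep[c] + amp[c] + pi[c] + 2 h[c]",
      gpr = "PPS1", sub = "gluconeogenesis"),
    # --- pyruvate to acetyl-CoA, TCA sketch, glutamate ---
    R("PDH", "pyr[c] + coa[c] + nad[c] -> accoa[c] + co2[c] + nadh[c]",
      gpr = "PDA1 and PDB1", sub = "central"),
    R("PC", "pyr[c] + co2[c] + atp[c] + h2o[c] -> oaa[c] + adp[c] + pi[c] + 2 h[c]",
      gpr = "PYC1", sub = "central"),
    R("CS", "accoa[c] + h2o[c] + oaa[c] -> cit[c] + coa[c] + h[c]",
      gpr = "CIT1", sub = "tca"),
    R("ACONT", "cit[c] <=> icit[c]", lb = -1000, gpr = "ACO1", sub = "tca"),
    R("ICDHy", "icit[c] + nadp[c] -> akg[c] + co2[c] + nadph[c]",
      gpr = "IDP1", sub = "tca"),
    R("GLUDy",
      "akg[c] + nh4[c] + nadph[c] + h[c] -> glu__L[c] + h2o[c] + nadp[c]",
      gpr = "GDH1", sub = "nitrogen"),
    # --- amino acids ---
    R("ALATA", "pyr[c] + glu__L[c] -> ala__L[c] + akg[c]", gpr = "ALT1",
      sub = "amino acids"),
    R("SERS",
      "3pg[c] + glu__L[c] + nad[c] + h2o[c] -> ser__L[c] + akg[c] + nadh[c] + pi[c] + h[c]",
      gpr = "SER1", sub = "amino acids",
      name = "serine synthesis (lumped)"),
    R("CYSS",
      "ser__L[c] + accoa[c] + so3[c] + 3 nadph[c] + 4 h[c] -> cys__L[c] + ac[c] + coa[c] + 3 h2o[c] + 3 nadp[c]",
      gpr = "CYS1", sub = "amino acids",
      name = "sulfite assimilation + cysteine synthesis (lumped)"),
    # --- pentose phosphate pathway ---
    R("G6PDH2",
      "g6p[c] + 2 nadp[c] + h2o[c] -> ru5p__D[c] + co2[c] + 2 nadph[c] + 2 h[c]",
      gpr = "ZWF1", sub = "ppp", name = "oxidative PPP (lumped)"),
    R("RPI", "ru5p__D[c] <=> r5p[c]", lb = -1000, gpr = "RKI1", sub = "ppp"),
    R("RPE", "ru5p__D[c] <=> xu5p__D[c]", lb = -1000, gpr = "RPE1",
      sub = "ppp"),
    R("TKT1", "xu5p__D[c] + r5p[c] <=> g3p[c] + s7p[c]", lb = -1000,
      gpr = "TKL1", sub = "ppp"),
    R("TALA", "g3p[c] + s7p[c] <=> e4p[c] + f6p[c]", lb = -1000,
      gpr = "TAL1", sub = "ppp"),
    R("TKT2", "xu5p__D[c] + e4p[c] <=> f6p[c] + g3p[c]", lb = -1000,
      gpr = "TKL1", sub = "ppp"),
    # --- shikimate pathway ---
    R("DDPA", "e4p[c] + pep[c] + h2o[c] -> 3ddah7p[c] + pi[c]",
      gpr = "ARO3", sub = "shikimate"),
    R("DHQS", "3ddah7p[c] -> dqt[c] + pi[c]", gpr = "ARO1",
      sub = "shikimate"),
    R("DHQTi", "dqt[c] -> dhsk[c] + h2o[c]", gpr = "ARO1",
      sub = "shikimate"),
    R("SHK3D", "dhsk[c] + nadph[c] + h[c] -> sme[c] + nadp[c]",
      gpr = "ARO1", sub = "shikimate"),
    R("SHKK", "sme[c] + atp[c] -> sme3p[c] + adp[c] + h[c]", gpr = "ARO1",
      sub = "shikimate"),
    R("PSCVT", "sme3p[c] + pep[c] -> 3psme[c] + pi[c]", gpr = "ARO1",
      sub = "shikimate"),
    R("CHORS", "3psme[c] -> chor[c] + pi[c]", gpr = "ARO2",
      sub = "shikimate"),
    R("CHORM", "chor[c] -> pphn[c]", gpr = "ARO7", sub = "shikimate"),
    # --- aromatic amino acids ---
    R("PPND", "pphn[c] + nad[c] -> 34hpp[c] + co2[c] + nadh[c]",
      gpr = "TYR1", sub = "aromatic"),
    R("TYRTA", "34hpp[c] + glu__L[c] -> tyr__L[c] + akg[c]", gpr = "AAT2",
      sub = "aromatic"),
    R("PPNDH", "pphn[c] + h[c] -> phpyr[c] + h2o[c] + co2[c]",
      gpr = "PHA2", sub = "aromatic"),
    R("PHETA", "phpyr[c] + glu__L[c] -> phe__L[c] + akg[c]", gpr = "AAT2",
      sub = "aromatic"),
    # --- phenylpropanoid / stilbene ---
    R("TAL", "tyr__L[c] -> couma[c] + nh4[c]", gpr = "PTAL",
      sub = "phenylpropanoid", name = "tyrosine ammonia-lyase"),
    R("PAL", "phe__L[c] -> cinnm[c] + nh4[c]", gpr = "PTAL",
      sub = "phenylpropanoid", name = "phenylalanine ammonia-lyase"),
    R("C4H",
      "cinnm[c] + o2[c] + nadph[c] + h[c] -> couma[c] + nadp[c] + h2o[c]",
      gpr = "C4H", sub = "phenylpropanoid", name = "cinnamate 4-hydroxylase"),
    R("4CL", "couma[c] + coa[c] + atp[c] -> 4cmcoa[c] + amp[c] + ppi[c] + h[c]",
      gpr = "4CL", sub = "phenylpropanoid",
      name = "4-coumarate-CoA ligase"),
    R("ACC",
      "accoa[c] + co2[c] + atp[c] + h2o[c] -> malcoa[c] + adp[c] + pi[c] + 2 h[c]",
      gpr = "ACC1", sub = "malonyl-CoA", name = "acetyl-CoA carboxylase"),
    R("CHS_STS",
      "4cmcoa[c] + 3 malcoa[c] + 3 h[c] -> resv[c] + 4 co2[c] + 4 coa[c]",
      gpr = "CHS", sub = "stilbene",
      name = "chalcone synthase acting as stilbene synthase"),
    R("CHS_NAR",
      "4cmcoa[c] + 3 malcoa[c] + 3 h[c] -> naring[c] + 3 co2[c] + 4 coa[c]",
      gpr = "CHS", sub = "flavonoid", name = "naringenin-chalcone synthase"),
    R("ROMT", "resv[c] + 2 amet[c] -> ptsb[c] + 2 ahcys[c] + 2 h[c]",
      gpr = "ROMT", sub = "stilbene",
      name = "resveratrol O-methyltransferase"),
    R("P450R",
      "resv[c] + o2[c] + nadph[c] + h[c] -> pice[c] + nadp[c] + h2o[c]",
      gpr = "CYP1B1", sub = "stilbene", name = "resveratrol 3'-hydroxylase"),
    # --- ethanol assimilation ---
    R("ADH", "etoh[c] + nad[c] <=> acald[c] + nadh[c] + h[c]", lb = -1000,
      gpr = "ADH1", sub = "ethanol"),
    R("ALDD", "acald[c] + nad[c] + h2o[c] -> ac[c] + nadh[c] + 2 h[c]",
      gpr = "ALD4", sub = "ethanol"),
    R("g0770", "ac[c] + coa[c] + atp[c] -> h[c] + accoa[c] + ppi[c] + amp[c]",
      gpr = "ACS1", sub = "ethanol", name = "acetyl-CoA synthetase"),
    # --- rhamnose utilization ---
    R("RMND", "rmn[c] + nadp[c] -> rmnl[c] + nadph[c] + h[c]", gpr = "RHD1",
      sub = "rhamnose", name = "L-rhamnose:NADP+ 1-oxidoreductase"),
    R("RMNL", "rmnl[c] + h2o[c] -> rmnt[c] + h[c]", gpr = "RHL1",
      sub = "rhamnose", name = "rhamnonolactonase"),
    R("RMNCAT", "rmnt[c] + 2 nad[c] -> 2 pyr[c] + 2 nadh[c] + 3 h[c]",
      gpr = "RHC1", sub = "rhamnose",
      name = "rhamnonate catabolism to pyruvate (lumped)"),
    # --- energy metabolism ---
    R("NADHOR",
      "nadh[c] + 3.5 h[c] + 0.5 o2[c] + 2.5 adp[c] + 2.5 pi[c] -> nad[c] + 2.5 atp[c] + 3.5 h2o[c]",
      sub = "energy", name = "respiratory chain, P/O 2.5 (lumped)"),
    R("THD", "nadh[c] + nadp[c] <=> nad[c] + nadph[c]", lb = -1000,
      sub = "energy", name = "transhydrogenase"),
    R("ADK1", "amp[c] + atp[c] <=> 2 adp[c]", lb = -1000, gpr = "ADK1",
      sub = "energy"),
    R("PPA", "ppi[c] + h2o[c] -> 2 pi[c]", gpr = "IPP1", sub = "energy",
      name = "inorganic pyrophosphatase"),
    R("ATPM", "atp[c] + h2o[c] -> adp[c] + pi[c] + h[c]", sub = "maintenance",
      name = "non-growth ATP maintenance"),
    # --- macromolecule precursor synthesis (lumped) ---
    R("MNLS", "f6p[c] + nadh[c] + h[c] + h2o[c] -> mnl[c] + nad[c] + pi[c]",
      gpr = "MTD1", sub = "storage", name = "mannitol synthesis (lumped)"),
    R("GLUCANS", "g6p[c] -> glucan[c] + pi[c]", gpr = "GSY1",
      sub = "cell wall", name = "glucan chain extension (lumped)"),
    R("FAS",
      "accoa[c] + 7 malcoa[c] + 14 nadph[c] + 20 h[c] -> hdca[c] + 7 co2[c] + 8 coa[c] + 14 nadp[c] + 6 h2o[c]",
      gpr = "FAS1 and FAS2", sub = "lipid",
      name = "fatty acid synthase (lumped to palmitate)"),
    R("DAMPS",
      "r5p[c] + 5 nh4[c] + 5 co2[c] + 6 nadph[c] + h[c] -> damp[c] + 12 h2o[c] + 6 nadp[c]",
      gpr = "ADE1", sub = "nucleotide", name = "dAMP synthesis (lumped)"),
    R("DTMPS",
      "r5p[c] + 2 nh4[c] + 5 co2[c] + 9 nadph[c] + 7 h[c] -> dtmp[c] + 10 h2o[c] + 9 nadp[c]",
      gpr = "TMP1", sub = "nucleotide", name = "dTMP synthesis (lumped)"),
    R("DGMPS",
      "r5p[c] + 5 nh4[c] + 5 co2[c] + 5 nadph[c] -> dgmp[c] + 11 h2o[c] + 5 nadp[c]",
      gpr = "GUA1", sub = "nucleotide", name = "dGMP synthesis (lumped)"),
    R("DCMPS",
      "r5p[c] + 3 nh4[c] + 4 co2[c] + 6 nadph[c] + 3 h[c] -> dcmp[c] + 9 h2o[c] + 6 nadp[c]",
      gpr = "URA2", sub = "nucleotide", name = "dCMP synthesis (lumped)"),
    # --- sinks and demands ---
    R("SK_amet", "amet[c] ->", lb = -1000, kind = "sink", sub = "sink",
      name = "S-adenosylmethionine sink"),
    R("SK_ahcys", "ahcys[c] ->", lb = -1000, kind = "sink", sub = "sink",
      name = "S-adenosylhomocysteine sink"),
    R("SK_ash", "ash[c] ->", lb = -1000, kind = "sink", sub = "sink",
      name = "ash sink"),
    R("DM_hdca", "hdca[c] ->", kind = "demand", sub = "lipid",
      name = "fatty-acid drain"),
    R("DM_naring", "naring[c] ->", kind = "demand", sub = "flavonoid",
      name = "naringenin drain")
  )
}

#' Molar masses of the mini-model biomass monomers
#'
#' Computed from the metabolite formulas, plus an assigned pseudo molar
#' mass for the non-elemental ash species.
#'
#' @return Named numeric vector in g/mmol.
#' @export
mini_monomer_masses <- function() {
  mets <- mini_metabolites()
  mons <- c("glucan[c]", "glu__L[c]", "ala__L[c]", "ser__L[c]", "cys__L[c]",
            "phe__L[c]", "tyr__L[c]", "mnl[c]", "hdca[c]",
            "damp[c]", "dtmp[c]", "dgmp[c]", "dcmp[c]")
  mm <- vapply(mons, function(m) {
    molar_mass(mets$formula[match(m, mets$id)])
  }, numeric(1))
  c(mm, "ash[c]" = 0.1)
}

#' Biomass composition of the synthetic network
#'
#' Macromolecular fractions: 32% cell wall, 20% protein, 15% mannitol,
#' 15% ash, 14% lipid and 4% nucleic acid. Monomer tables are the
#' mini-network's stand-ins: glucan for the wall, six amino acids for
#' protein, palmitate for lipid, and the four dNMPs at mole fractions set
#' by the genome GC content (50.96% by default), converted to mass
#' fractions. GAM defaults to 60 mmol ATP/gDW and NGAM to 1.0 mmol
#' ATP/gDW/h.
#'
#' @param gc Genome GC content used for the nucleotide split.
#' @param gam,ngam ATP maintenance parameters.
#' @return A [biomass_composition()].
#' @export
composition_fixture <- function(gc = 0.5096, gam = 60, ngam = 1.0) {
  mm <- mini_monomer_masses()
  nuc_moles <- nucleotide_fractions_from_gc(gc)
  names(nuc_moles) <- c("damp[c]", "dtmp[c]", "dgmp[c]", "dcmp[c]")
  biomass_composition(
    macro = c(cell_wall = 0.32, protein = 0.20, mannitol = 0.15,
              ash = 0.15, lipid = 0.14, nucleic_acid = 0.04),
    monomers = list(
      cell_wall = c("glucan[c]" = 1),
      protein = c("glu__L[c]" = 0.25, "ala__L[c]" = 0.15, "ser__L[c]" = 0.15,
                  "cys__L[c]" = 0.10, "phe__L[c]" = 0.20, "tyr__L[c]" = 0.15),
      mannitol = c("mnl[c]" = 1),
      ash = c("ash[c]" = 1),
      lipid = c("hdca[c]" = 1),
      nucleic_acid = mole_to_mass_fractions(nuc_moles, mm)
    ),
    gam = gam, ngam = ngam
  )
}

#' Generate the synthetic mini metabolic network
#'
#' Builds the deterministic mini-network (see the package vignette for the
#' topology). The default build takes no random input and is
#' bit-reproducible; `seed`/`jitter` optionally perturb internal reaction
#' upper bounds for robustness experiments.
#'
#' @param include_rhamnose Include the rhamnose transporter and
#'   L-rhamnose:NADP+ 1-oxidoreductase. When FALSE the downstream
#'   catabolism and the rhamnose exchange remain, leaving a growth gap
#'   that [gap_fill()] can close from [mini_universal_set()].
#' @param include_ethanol Include the ethanol assimilation route
#'   (transporter, ADH, aldehyde dehydrogenase and the acetate-activating
#'   reaction g0770).
#' @param knockout Reaction ids removed from the generated model; an
#'   unknown id is an error.
#' @param composition Biomass composition (default [composition_fixture()]).
#' @param seed,jitter Optional deterministic jitter: with `jitter > 0`,
#'   internal non-exchange upper bounds are scaled by
#'   `1 + runif(-jitter, jitter)` under `seed`.
#' @return A validated `metabolic_model` with the biomass reaction as
#'   objective and NGAM applied.
#' @examples
#' m <- mini_model()
#' glance(m)
#' @export
mini_model <- function(include_rhamnose = TRUE, include_ethanol = TRUE,
                       knockout = character(), composition = NULL,
                       seed = NULL, jitter = 0) {
  mets <- mini_metabolites()
  rxns <- mini_reactions()
  drop <- character(0)
  if (!include_rhamnose) drop <- c(drop, "RMNt", "RMND")
  if (!include_ethanol) drop <- c(drop, "ETOHt", "ADH", "ALDD", "g0770",
                                  "EX_etoh_e")
  rxns <- rxns[!(rxns$id %in% drop), ]
  if (length(knockout) > 0) {
    missing <- setdiff(knockout, rxns$id)
    if (length(missing) > 0) {
      stop("knockout of absent reaction(s): ", paste(missing, collapse = ", "))
    }
    rxns <- rxns[!(rxns$id %in% knockout), ]
  }
  composition <- composition %||na% composition_fixture()
  biomass <- build_biomass_reaction(composition, mini_monomer_masses())
  rxns <- dplyr::bind_rows(rxns, biomass)
  if (jitter > 0) {
    if (is.null(seed)) stop("jitter requires a seed")
    internal <- which(!(rxns$kind %in% c("exchange", "biomass")))
    fac <- withr::with_seed(seed,
      1 + stats::runif(length(internal), -jitter, jitter))
    rxns$ub[internal] <- ifelse(is.finite(rxns$ub[internal]),
                                rxns$ub[internal] * fac, rxns$ub[internal])
  }
  model <- metabolic_model(
    metabolites = mets, reactions = rxns,
    genes = unique(unlist(lapply(rxns$gpr, gpr_genes))),
    objective = c(BIOMASS = 1),
    notes = "synthetic mini-network (deterministic fixture)"
  )
  add_ngam(model, composition$ngam)
}

#' Minimal medium for the mini-network
#'
#' Basic nutrient exchanges (carbon source, water/protons, oxygen,
#' ammonium, sulfite, phosphate), following the convention of opening the
#' basic components at 1000 mmol/gDW/h and constraining only the carbon
#' source when a defined rate is studied.
#'
#' @param glucose Maximum glucose uptake rate (mmol/gDW/h).
#' @return Named uptake vector for [set_medium()].
#' @export
mini_minimal_medium <- function(glucose = 1000) {
  c(EX_glc__D_e = glucose, EX_h2o_e = 1000, EX_h_e = 1000, EX_o2_e = 1000,
    EX_nh4_e = 1000, EX_so3_e = 1000, EX_pi_e = 1000)
}

#' Rich (PDB-like) medium for the mini-network
#'
#' Approximates a rich broth by glucose at 2.0 mmol/gDW/h plus the
#' network's amino-acid exchanges at 0.01 mmol/gDW/h, with the basic
#' minerals unconstrained.
#'
#' @param glucose,amino_acid Uptake rates (mmol/gDW/h).
#' @return Named uptake vector for [set_medium()].
#' @export
mini_rich_medium <- function(glucose = 2.0, amino_acid = 0.01) {
  c(mini_minimal_medium(glucose = glucose),
    EX_phe__L_e = amino_acid, EX_tyr__L_e = amino_acid)
}

#' Production-analysis state of the mini-network
#'
#' Applies the constraint set used for cofactor/robustness analyses of
#' resveratrol formation: glucose uptake fixed by `glucose`, trace
#' phenylalanine/tyrosine uptake, growth pinned to `growth`, objective the
#' resveratrol exchange.
#'
#' @param model A mini-network model.
#' @param glucose Glucose uptake (mmol/gDW/h).
#' @param growth Pinned growth rate (1/h).
#' @param aromatic_uptake Trace phe/tyr uptake (mmol/gDW/h).
#' @return The constrained model (objective unchanged; pass
#'   `objective = "EX_resv_e"` to [solve_fba()]).
#' @export
mini_production_state <- function(model, glucose = 1.0, growth = 0.055,
                                  aromatic_uptake = 1e-6) {
  med <- c(mini_minimal_medium(glucose = glucose),
           EX_phe__L_e = aromatic_uptake, EX_tyr__L_e = aromatic_uptake)
  model |>
    set_medium(med) |>
    fix_growth(growth)
}

#' Universal reaction set for gap filling the mini-network
#'
#' Candidate reactions usable by [gap_fill()]: the rhamnose transporter
#' and L-rhamnose:NADP+ 1-oxidoreductase (the two reactions whose absence
#' blocks growth on rhamnose), a phosphofructokinase copy, and two
#' redundant decoys that never help (a second pyrophosphatase and
#' transhydrogenase).
#'
#' @return A reaction tibble in the model dialect.
#' @export
mini_universal_set <- function() {
  all <- mini_reactions()
  picks <- all[match(c("PPA", "THD", "RMNt", "RMND", "PFK"), all$id), ]
  picks$id <- c("U_PPA2", "U_THD2", "RMNt", "RMND", "PFK")
  picks$name <- paste0(picks$name, " (universal candidate)")
  picks
}

#' Substrate-to-exchange mapping for phenotype tests on the mini-network
#'
#' @return A tibble with columns `substrate`, `role`, `exchange`,
#'   `observed`, suitable for [sole_source_growth_test()].
#' @export
mini_substrate_table <- function() {
  tibble::tribble(
    ~substrate, ~role, ~exchange, ~observed,
    "glucose", "carbon", "EX_glc__D_e", "+",
    "sucrose", "carbon", "EX_sucr_e", "+",
    "rhamnose", "carbon", "EX_rmn_e", "+",
    "ammonium", "nitrogen", "EX_nh4_e", "+"
  )
}
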