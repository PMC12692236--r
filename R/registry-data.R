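# Built-in steroidogenesis panel: 50 conjugated urinary steroid-hormone (SH)
# metabolites retained after reproducibility filtering, annotated with their
# hormone group, phase-II conjugation class, molar mass and LOD, plus the
# cohort calibration medians/IQRs (umol/L) used by the synthetic generator.
#
# Molar masses are documented approximations: average aglycone mass plus
# conjugate increments (glucuronide +176.1, sulfate +80.1, disulfate +160.1,
# mixed sulfoglucoconjugate +256.2 g/mol).

sh_panel_table <- function() {
  tibble::tribble(
    ~id,              ~full_name,                                        ~hormone_group,            ~molar_mass, ~median_bisc, ~iqr_bisc, ~median_inma, ~iqr_inma,
    "5PD-20one-S",    "17-hydroxy-5-pregnenolone-3-sulfate",             "17-hydroxy-pregnenolone", 412.5,  1.99, 2.64, 2.75, 3.85,
    "PT-G",           "Pregnantriol-glucuronide",                        "17-hydroxy-progesterone", 512.6,  3.27, 2.09, 4.30, 3.84,
    "PT-diS",         "Pregnantriol-disulfate",                          "17-hydroxy-progesterone", 496.6,  0.05, 0.07, 0.07, 0.12,
    "A-S",            "11-dehydrocorticosterone-sulfate",                "Corticosterone",          424.5,  0.30, 0.20, 0.35, 0.46,
    "B-S",            "Corticosterone-sulfate",                          "Corticosterone",          426.6,  0.39, 0.30, 0.59, 0.70,
    "20DHE-G",        "20-dihydrocortisone-glucuronide",                 "Cortisol",                538.6,  0.10, 0.10, 0.11, 0.15,
    "20aDHF-G",       "20alpha-dihydrocortisol-glucuronide",             "Cortisol",                540.6,  0.03, 0.04, 0.07, 0.08,
    "20bDHF-G",       "20beta-dihydrocortisol-glucuronide",              "Cortisol",                540.6,  0.31, 0.30, 0.33, 0.48,
    "Cortolone-G_1",  "20alpha-Cortolone-glucuronide",                   "Cortisol",                542.7,  2.33, 1.76, 3.85, 4.31,
    "Cortolone-G_2",  "20beta-Cortolone-glucuronide",                    "Cortisol",                542.7,  1.08, 0.86, 2.50, 2.96,
    "E-G",            "Cortisone-glucuronide",                           "Cortisol",                536.6,  0.33, 0.22, 0.58, 0.69,
    "E-S",            "Cortisone-sulfate",                               "Cortisol",                440.5,  0.03, 0.02, 0.04, 0.04,
    "F-G",            "Cortisol-glucuronide",                            "Cortisol",                538.6,  0.08, 0.06, 0.22, 0.21,
    "F-S",            "Cortisol-sulfate",                                "Cortisol",                442.5,  0.18, 0.12, 0.28, 0.30,
    "THE-G",          "Tetrahydrocortisone-glucuronide",                 "Cortisol",                540.6,  1.74, 1.46, 3.56, 3.78,
    "16OH-DHEAS_1",   "16beta-hydroxy-DHEA-sulfate",                     "DHEA",                    384.5,  0.87, 0.65, 0.63, 0.86,
    "16OH-DHEAS_2",   "16alpha-hydroxy-DHEA-sulfate",                    "DHEA",                    384.5,  0.60, 0.85, 0.85, 1.44,
    "16OHDHEA-diS_1", "16beta-hydroxy-DHEA-disulfate",                   "DHEA",                    464.5,  0.34, 0.38, 0.39, 0.51,
    "16OHDHEA-diS_2", "16alpha-hydroxy-DHEA-disulfate",                  "DHEA",                    464.5,  0.12, 0.13, 0.14, 0.21,
    "5AD-diS_1",      "5-androsten-3beta,17beta-diol-disulfate",         "DHEA",                    450.6,  0.04, 0.04, 0.05, 0.07,
    "5AD-diS_2",      "5-androsten-3alpha,17beta-diol-disulfate",        "DHEA",                    450.6,  0.11, 0.10, 0.16, 0.20,
    "DHEA-S",         "Dehydroepiandrosterone-sulfate",                  "DHEA",                    368.5,  0.12, 0.33, 0.26, 0.97,
    "epiAN-S",        "Epiandrosterone-sulfate",                         "DHEA",                    370.5,  0.07, 0.14, 0.13, 0.26,
    "E1-G",           "Estrone-glucuronide",                             "Estradiol",               446.5,  0.73, 0.70, 1.12, 1.25,
    "E1-S",           "Estrone-sulfate",                                 "Estradiol",               350.4,  1.59, 3.22, 2.22, 4.89,
    "E2-S",           "Estradiol-sulfate",                               "Estradiol",               352.4,  0.02, 0.03, 0.03, 0.05,
    "E3-G",           "Estriol-glucuronide",                             "Estriol",                 464.5,  2.69, 1.82, 2.93, 2.18,
    "E3-S",           "Estriol-sulfate",                                 "Estriol",                 368.4,  0.76, 0.90, 1.02, 1.31,
    "E3-SG",          "Estriol-sulfoglucoconjugate",                     "Estriol",                 544.6,  1.05, 1.22, 1.19, 1.46,
    "E4-SG",          "Estetrol-sulfoglucoconjugate",                    "Estriol",                 560.6,  0.03, 0.04, 0.03, 0.05,
    "21OH-5P-diS",    "21-Hydroxypregnenolone-disulfate",                "Pregnenolone",            492.6,  0.20, 0.15, 0.28, 0.24,
    "5PD-G",          "5-Pregnendiol-glucuronide",                       "Pregnenolone",            494.7, 45.04, 30.24, 52.53, 48.78,
    "5PD-SG",         "5-Pregnendiol-sulfoglucoconjugate",               "Pregnenolone",            574.7,  0.47, 0.44, 0.52, 0.62,
    "5PD-diS",        "5-Pregnendiol-disulfate",                         "Pregnenolone",            478.6,  2.46, 1.80, 3.17, 2.95,
    "PD-G",           "Pregnandiol-glucuronide",                         "Progesterone",            496.7, 72.62, 43.54, 76.60, 57.04,
    "PD-SG_1",        "5alpha-Pregnandiol-3beta-sulfate-20alpha-glucuronide", "Progesterone",       576.7,  1.93, 2.27, 1.64, 2.07,
    "PD-SG_2",        "Pregnandiol-sulfoglucoconjugate isomer 2",        "Progesterone",            576.7,  0.95, 1.36, 0.68, 1.17,
    "PD-SG_4",        "Pregnandiol-sulfoglucoconjugate isomer 4",        "Progesterone",            576.7,  2.66, 2.46, 2.82, 3.15,
    "PD-SG_5",        "Pregnandiol-sulfoglucoconjugate isomer 5",        "Progesterone",            576.7,  1.09, 0.98, 1.14, 1.20,
    "PD-S_1",         "5alpha-Pregnan-3beta,20alpha-diol-20-sulfate",    "Progesterone",            400.6,  0.61, 0.73, 0.77, 1.22,
    "PD-S_2",         "5beta-Pregnan-3alpha,20alpha-diol-20-sulfate",    "Progesterone",            400.6,  6.06, 7.89, 7.06, 11.94,
    "PD-diS_1",       "5alpha-Pregnan-3beta,20alpha-diol-disulfate",     "Progesterone",            480.6,  1.61, 1.05, 1.75, 1.28,
    "PD-diS_3",       "5beta-Pregnan-3alpha,20alpha-diol-disulfate",     "Progesterone",            480.6,  0.04, 0.04, 0.07, 0.09,
    "PD_diS_2",       "5alpha-Pregnan-3alpha,20alpha-diol-disulfate",    "Progesterone",            480.6,  0.43, 0.41, 0.52, 0.67,
    "AN-S",           "Androsterone-sulfate",                            "Testosterone",            370.5,  0.46, 0.63, 0.83, 1.29,
    "Andros-G",       "Androsterone-glucuronide",                        "Testosterone",            466.6,  3.25, 2.63, 5.62, 6.00,
    "Etio-G",         "Etiocholanolone-glucuronide",                     "Testosterone",            466.6,  1.09, 1.12, 2.27, 2.82,
    "Etio-S",         "Etiocholanolone-sulfate",                         "Testosterone",            370.5,  0.36, 0.45, 0.78, 1.09,
    "T-G",            "Testosterone-glucuronide",                        "Testosterone",            464.6,  0.01, 0.01, 0.02, 0.02,
    "T-S",            "Testosterone-sulfate",                            "Testosterone",            368.5,  0.02, 0.02, 0.02, 0.03
  )
}

# hormone group -> steroid family
sh_family_map <- c(
  "DHEA" = "androgen", "Testosterone" = "androgen",
  "Estradiol" = "estrogen", "Estriol" = "estrogen",
  "Pregnenolone" = "progestogen", "Progesterone" = "progestogen",
  "17-hydroxy-pregnenolone" = "progestogen", "17-hydroxy-progesterone" = "progestogen",
  "Cortisol" = "corticosteroid", "Corticosterone" = "corticosteroid"
)

#' Conjugation class implied by a metabolite id suffix
#'
#' Panel ids follow the field's suffix convention: `-G` glucuronide, `-S`
#' sulfate, `-diS` disulfate, `-SG` mixed sulfoglucoconjugate (a trailing
#' `_k` isomer index is ignored).
#'
#' @param id Character vector of metabolite ids.
#' @return Character vector of conjugation classes.
#' @export
conjugation_from_id <- function(id) {
  stem <- sub("_[0-9]+$", "", id)
  dplyr::case_when(
    grepl("diS$", stem) ~ "disulfate",
    grepl("SG$", stem) ~ "sulfoglucoconjugate",
    grepl("G$", stem) ~ "glucuronide",
    grepl("S$", stem) ~ "sulfate",
    TRUE ~ NA_character_
  )
}

metabolites_of <- function(panel, group) panel$id[panel$hormone_group %in% group]

conjugates_of <- function(panel, group, classes) {
  sub <- panel[panel$hormone_group %in% group & panel$conjugation %in% classes, ]
  sub$id
}

# The 13 sums, 9 S/G ratios and 17 enzyme-activity ratios. The exact
# compositions are registry data (overridable): sums are the four family
# totals plus nine hormone-group totals; S/G ratios put sulfate + disulfate
# conjugates over glucuronides within a family or hormone group; enzyme
# ratios are product/precursor molar sets read off the steroidogenesis
# pathway for each named enzyme.
sh_derived_table <- function(metabolites) {
  p <- metabolites
  fam <- function(f) p$id[p$family == f]
  grp <- function(g) metabolites_of(p, g)
  sulf <- c("sulfate", "disulfate")

  sums <- list(
    total_androgens = fam("androgen"),
    total_estrogens = fam("estrogen"),
    total_progestogens = fam("progestogen"),
    total_corticosteroids = fam("corticosteroid"),
    total_dhea = grp("DHEA"),
    total_testosterone = grp("Testosterone"),
    total_cortisol = grp("Cortisol"),
    total_corticosterone = grp("Corticosterone"),
    total_estradiol = grp("Estradiol"),
    total_estriol = grp("Estriol"),
    total_pregnenolone = grp("Pregnenolone"),
    total_progesterone = grp("Progesterone"),
    total_17oh_progesterone = grp("17-hydroxy-progesterone")
  )

  sg_num <- function(scope, by_family = FALSE) {
    if (by_family) p$id[p$family == scope & p$conjugation %in% sulf]
    else conjugates_of(p, scope, sulf)
  }
  sg_den <- function(scope, by_family = FALSE) {
    if (by_family) p$id[p$family == scope & p$conjugation == "glucuronide"]
    else conjugates_of(p, scope, "glucuronide")
  }
  sg <- list(
    sg_androgens = list(sg_num("androgen", TRUE), sg_den("androgen", TRUE)),
    sg_estrogens = list(sg_num("estrogen", TRUE), sg_den("estrogen", TRUE)),
    sg_progestogens = list(sg_num("progestogen", TRUE), sg_den("progestogen", TRUE)),
    sg_corticosteroids = list(sg_num("corticosteroid", TRUE), sg_den("corticosteroid", TRUE)),
    sg_cortisol = list(sg_num("Cortisol"), sg_den("Cortisol")),
    sg_testosterone = list(sg_num("Testosterone"), sg_den("Testosterone")),
    sg_progesterone = list(sg_num("Progesterone"), sg_den("Progesterone")),
    sg_estriol = list(sg_num("Estriol"), sg_den("Estriol")),
    sg_pregnenolone = list(sg_num("Pregnenolone"), sg_den("Pregnenolone"))
  )

  enz <- list(
    enz_aromatase = list("aromatase", grp("Estradiol"), grp("Testosterone")),
    enz_cyp17_hydroxylase = list(
      "CYP17 (17alpha-hydroxylase)",
      c(grp("17-hydroxy-pregnenolone"), grp("17-hydroxy-progesterone")),
      c(grp("Pregnenolone"), grp("Progesterone"))
    ),
    enz_cyp17_lyase = list(
      "CYP17 (17,20-lyase)", grp("DHEA"),
      c(grp("17-hydroxy-pregnenolone"), grp("17-hydroxy-progesterone"))
    ),
    enz_hsd3b_progestogens = list("3beta-HSD (progestogens)", grp("Progesterone"), grp("Pregnenolone")),
    enz_hsd3b_androgens = list("3beta-HSD (androgens)", grp("Testosterone"), grp("DHEA")),
    enz_cyp21 = list(
      "21-hydroxylase", fam("corticosteroid"),
      c(grp("Progesterone"), grp("17-hydroxy-progesterone"))
    ),
    enz_hsd11b1 = list(
      "11beta-HSD1", c("F-G", "F-S", "20aDHF-G", "20bDHF-G"),
      c("E-G", "E-S", "20DHE-G", "THE-G")
    ),
    enz_hsd11b2 = list(
      "11beta-HSD2", c("E-G", "E-S", "20DHE-G", "THE-G"),
      c("F-G", "F-S", "20aDHF-G", "20bDHF-G")
    ),
    enz_hsd11b_corticosterone = list("11beta-HSD (corticosterone branch)", "B-S", "A-S"),
    enz_20a_reductase = list("20alpha-reductase", c("20aDHF-G", "Cortolone-G_1"), c("F-G", "F-S")),
    enz_20b_reductase = list("20beta-reductase", c("20bDHF-G", "Cortolone-G_2"), c("F-G", "F-S")),
    enz_5a_reductase_3ahsd = list("5alpha-reductase + 3alpha-HSD", c("Andros-G", "AN-S"), c("T-G", "T-S")),
    enz_5b_reductase_3ahsd = list("5beta-reductase + 3alpha-HSD", c("Etio-G", "Etio-S"), c("T-G", "T-S")),
    enz_5a5b_ratio = list("5alpha/5beta reduction balance", c("Andros-G", "AN-S"), c("Etio-G", "Etio-S")),
    enz_5a_reductase_progestogens = list(
      "5alpha-reductase (progestogens)",
      c("PD-diS_1", "PD_diS_2", "PD-S_1", "PD-SG_1"), c("PD-diS_3", "PD-S_2")
    ),
    enz_hsd17b = list("17beta-HSD", "E2-S", c("E1-G", "E1-S")),
    enz_16a_hydroxylase = list(
      "16-hydroxylase (DHEA branch)",
      c("16OH-DHEAS_1", "16OH-DHEAS_2", "16OHDHEA-diS_1", "16OHDHEA-diS_2"), "DHEA-S"
    )
  )

  dplyr::bind_rows(
    tibble::tibble(
      id = names(sums), feature_class = "sum", label = gsub("_", " ", names(sums)),
      numerator_ids = unname(sums), denominator_ids = list(character(0))
    ),
    tibble::tibble(
      id = names(sg), feature_class = "sg_ratio",
      label = paste("S/G ratio:", sub("^sg_", "", names(sg))),
      numerator_ids = unname(purrr::map(sg, 1)),
      denominator_ids = unname(purrr::map(sg, 2))
    ),
    tibble::tibble(
      id = names(enz), feature_class = "enzyme_ratio",
      label = unname(purrr::map_chr(enz, 1)),
      numerator_ids = unname(purrr::map(enz, 2)),
      denominator_ids = unname(purrr::map(enz, 3))
    )
  )
}
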