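# Reference tables printed in the source publications: the 18-SNP genome-wide
# CRP instrument membership and the 32-outcome panel bookkeeping. Per-SNP
# weight values are not shipped (they are not public print); tests and
# examples attach synthetic weights and say so.

#' The 18 genome-wide significant CRP instrument SNPs
#'
#' Membership of the 18-SNP genome-wide CRP genetic risk score: rsid, nearest
#' gene/locus, chromosome and 1-based position. Per-allele weights are not
#' included; supply your own (e.g. from a CRP meta-GWAS) or synthetic ones.
#' The three SNPs in \emph{PPP1R3B}, \emph{HNF1A} and \emph{APOC1} were absent
#' from the schizophrenia consortium data, leaving 15 usable there.
#'
#' @return A tibble with columns `rsid`, `locus`, `chrom`, `pos`,
#'   `in_scz_data` (logical: present in the schizophrenia summary data).
#' @export
grs_gwas_snps <- function() {
  tibble::tribble(
    ~rsid,        ~locus,     ~chrom, ~pos,
    "rs2847281",  "PTPN2",    "18",   12811593,
    "rs340029",   "RORA",     "15",   58682257,
    "rs6901250",  "GPRC6A",   "6",    117220718,
    "rs10745954", "ASCL1",    "12",   102007224,
    "rs4705952",  "IRF1",     "5",    131867517,
    "rs12037222", "PABPC4",   "1",    39837548,
    "rs12239046", "NLRP3",    "1",    245668218,
    "rs6734238",  "IL1F10",   "2",    113557501,
    "rs13233571", "BCL7B",    "7",    72609167,
    "rs9987289",  "PPP1R3B",  "8",    9220768,
    "rs1260326",  "GCKR",     "2",    27584444,
    "rs4129267",  "IL6R",     "1",    152692888,
    "rs1800961",  "HNF4A",    "20",   42475778,
    "rs4420065",  "LEPR",     "1",    5934049,
    "rs10521222", "SALL1",    "16",   49716211,
    "rs1183910",  "HNF1A",    "12",   119905190,
    "rs2794520",  "CRP",      "1",    157945440,
    "rs4420638",  "APOC1",    "19",   50114786
  ) |>
    dplyr::mutate(in_scz_data = !.data$locus %in% c("PPP1R3B", "HNF1A", "APOC1"))
}

#' The 32-outcome consortium panel
#'
#' Sample-size bookkeeping for the 32 somatic and psychiatric outcomes:
#' disease class, case/control counts where binary, and total sample size.
#' Used for instrument-strength F-statistics (with R-squared 0.02 for the
#' 4-SNP gene score and 0.05 for the 18-SNP genome-wide score).
#'
#' @return A tibble with columns `outcome`, `class`, `n_cases`, `n_controls`,
#'   `n_total`, `outcome_type`.
#' @export
outcome_panel <- function() {
  tb <- tibble::tribble(
    ~outcome,                          ~class,                     ~n_cases, ~n_controls, ~n_total,
    "Celiac disease",                  "autoimmune_inflammatory",  4533,     10750,       15283,
    "IBD (all types)",                 "autoimmune_inflammatory",  13020,    34774,       47794,
    "Crohn disease",                   "autoimmune_inflammatory",  6333,     15056,       21389,
    "Ulcerative colitis",              "autoimmune_inflammatory",  6687,     19718,       26405,
    "Psoriasis vulgaris",              "autoimmune_inflammatory",  4007,     4934,        8941,
    "Psoriatic arthritis",             "autoimmune_inflammatory",  1946,     4934,        6880,
    "Cutaneous psoriasis",             "autoimmune_inflammatory",  1363,     3517,        4880,
    "Rheumatoid arthritis",            "autoimmune_inflammatory",  5538,     20167,       25705,
    "Systemic lupus erythematous",     "autoimmune_inflammatory",  1311,     3340,        4651,
    "Systemic sclerosis",              "autoimmune_inflammatory",  2356,     5187,        7543,
    "Type 1 diabetes",                 "autoimmune_inflammatory",  9934,     16956,       26890,
    "Knee osteoarthritis",             "autoimmune_inflammatory",  5755,     18505,       24260,
    "Coronary artery disease",         "cardiovascular",           60801,    123504,      184305,
    "Systolic blood pressure",         "cardiovascular",           NA,       NA,          69368,
    "Diastolic blood pressure",        "cardiovascular",           NA,       NA,          69372,
    "Ischemic stroke (all types)",     "cardiovascular",           3548,     5972,        9520,
    "Ischemic stroke (cardioembolic)", "cardiovascular",           790,      5972,        6762,
    "Ischemic stroke (large vessel)",  "cardiovascular",           844,      5972,        6816,
    "Ischemic stroke (small vessel)",  "cardiovascular",           580,      5972,        6522,
    "Body mass index",                 "metabolic",                NA,       NA,          123865,
    "Type 2 diabetes",                 "metabolic",                6698,     15872,       22570,
    "Chronic kidney disease",          "metabolic",                6271,     68083,       74354,
    "eGFRcr",                          "metabolic",                NA,       NA,          74354,
    "Serum albumin level",             "metabolic",                NA,       NA,          53189,
    "Serum protein level",             "metabolic",                NA,       NA,          25537,
    "Amyotrophic lateral sclerosis",   "neurodegenerative",        4133,     8130,        12663,
    "Alzheimer disease",               "neurodegenerative",        4663,     8357,        13020,
    "Parkinson disease",               "neurodegenerative",        5333,     12019,       17352,
    "Autism",                          "psychiatric",              90,       1476,        1566,
    "Bipolar disorder",                "psychiatric",              7481,     9250,        16731,
    "Major depressive disorder",       "psychiatric",              9240,     9519,        18759,
    "Schizophrenia",                   "psychiatric",              34241,    45604,       79845
  )
  tb$outcome_type <- ifelse(is.na(tb$n_cases), "quantitative", "binary")
  tb
}
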