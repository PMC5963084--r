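# Frozen fixture of 24 published patient cases with aberrant PK or target
# expression affecting administered therapies. Each entry records a gene's
# reported Z-score, the feature column it was reported under (transport /
# metabolism / target) and the administered drugs it affects. A couple of
# obvious typesetting errors in the source table are normalized (gene symbol
# NR2I1 read as NR1I2; a decimal comma read as a decimal point).

published_case_data <- function() {
  # patient|cancer_type|age|stage|grade|tem_expected
  cases <- c(
    "TCGA-E2-A1LB|BRCA|41|2|NA|TRUE",
    "TCGA-E2-A158|BRCA|43|2|NA|TRUE",
    "TCGA-E2-A14V|BRCA|53|2|NA|FALSE",
    "TCGA-AO-A0J3|BRCA|67|2|NA|TRUE",
    "TCGA-BH-A0BA|BRCA|51|3|NA|TRUE",
    "TCGA-AO-A0JE|BRCA|53|3|NA|TRUE",
    "TCGA-09-0367|OV|67|3|3|FALSE",
    "TCGA-23-1123|OV|59|3|3|TRUE",
    "TCGA-24-1558|OV|73|3|3|TRUE",
    "TCGA-30-1860|OV|58|3|3|FALSE",
    "TCGA-61-1724|OV|47|3|3|FALSE",
    "TCGA-61-1741|OV|76|3|3|TRUE",
    "TCGA-CJ-4638|KIRC|46|4|4|TRUE",
    "TCGA-50-5072|LUAD|74|3|NA|TRUE",
    "TCGA-AP-A052|UCEC|59|4|3|FALSE",
    "TCGA-AP-A05D|UCEC|67|3|3|FALSE",
    "TCGA-AP-A0LI|UCEC|67|3|3|FALSE",
    "TCGA-AX-A0IS|UCEC|52|1|2|FALSE",
    "TCGA-AX-A1CR|UCEC|70|2|3|FALSE",
    "TCGA-BS-A0TE|UCEC|35|4|3|TRUE",
    "TCGA-CR-7404|HNSC|53|1|NA|TRUE",
    "TCGA-DQ-7589|HNSC|70|1|NA|TRUE",
    "TCGA-46-6026|LUSC|81|2|NA|TRUE",
    "TCGA-94-7033|LUSC|73|1|NA|FALSE")
  # patient|feature|gene|z|drug abbreviations
  entries <- c(
    "TCGA-E2-A1LB|metabolism|AKR1A1|3.01|Dox",
    "TCGA-E2-A1LB|transport|ABCC2|4.77|Pac",
    "TCGA-E2-A158|target|MAP2|-3.56|Pac",
    "TCGA-E2-A158|target|MAP4|-3.29|Pac",
    "TCGA-E2-A158|transport|ABCC1|2.27|Dox",
    "TCGA-E2-A14V|target|EGFR|-4.65|Lap",
    "TCGA-E2-A14V|metabolism|CYP2C8|2.2|Pac",
    "TCGA-AO-A0J3|target|MAP4|-3.11|Pac",
    "TCGA-AO-A0J3|transport|ABCC5|2.21|5FU,Meth",
    "TCGA-AO-A0J3|transport|FOLR1|-3.42|Meth",
    "TCGA-BH-A0BA|metabolism|NQO1|3.22|Dox",
    "TCGA-BH-A0BA|transport|ABCC2|3.09|Pac",
    "TCGA-AO-A0JE|transport|ABCC1|2.73|Pac,Dox",
    "TCGA-AO-A0JE|transport|ABCC2|3.86|Pac,Dox",
    "TCGA-09-0367|target|MAP2|-3.66|Pac",
    "TCGA-09-0367|target|MAP4|-3.96|Pac",
    "TCGA-09-0367|metabolism|NT5C|3.78|Gem",
    "TCGA-09-0367|transport|SLC31A1|-2.67|Car",
    "TCGA-23-1123|metabolism|NR1I2|3.42|Pac",
    "TCGA-23-1123|transport|RALBP1|4.17|Car,Dox",
    "TCGA-24-1558|target|MAP2|-4.71|Pac,Doc",
    "TCGA-24-1558|transport|ABCC1|6.49|Gem,Dox",
    "TCGA-24-1558|transport|ABCC10|2.66|Gem,Dox",
    "TCGA-30-1860|target|TOP2B|-4.39|Pac,Dox",
    "TCGA-30-1860|target|MAP2|-5.04|Pac,Dox",
    "TCGA-61-1724|target|MAP2|-4.57|Doc",
    "TCGA-61-1724|metabolism|DCTD|4.46|Gem",
    "TCGA-61-1741|metabolism|CYP2C8|3.19|Pac,Tam",
    "TCGA-61-1741|metabolism|NR1I2|3.94|Pac,Tam",
    "TCGA-61-1741|transport|SLC31A1|-3.21|Car",
    "TCGA-CJ-4638|metabolism|NT5C|3.84|Gem,5FU",
    "TCGA-CJ-4638|metabolism|UPB1|3.87|Gem,5FU",
    "TCGA-CJ-4638|metabolism|DPYS|2.33|Gem,5FU",
    "TCGA-50-5072|transport|ABCC2|5.12|Doc,Pac",
    "TCGA-AP-A052|metabolism|CMPK1|-4.12|Gem",
    "TCGA-AP-A052|metabolism|NR1I2|3.92|Pac",
    "TCGA-AP-A05D|target|MAPT|-3.05|Pac",
    "TCGA-AP-A05D|target|TUBB1|-2.43|Pac",
    "TCGA-AP-A05D|transport|SLC31A1|-3.7|Carb",
    "TCGA-AP-A0LI|target|MAP2|-5.57|Pac",
    "TCGA-AP-A0LI|target|MAPT|-2.21|Pac",
    "TCGA-AP-A0LI|transport|SLC31A1|-4.11|Carb",
    "TCGA-AX-A0IS|target|MAP2|-3.09|Pac",
    "TCGA-AX-A0IS|target|MAP4|-3.27|Pac",
    "TCGA-AX-A0IS|metabolism|DCTD|3.49|Gem",
    "TCGA-AX-A1CR|metabolism|NR1I2|3.18|Pac",
    "TCGA-AX-A1CR|transport|SLC31A1|-5.04|Carb",
    "TCGA-BS-A0TE|metabolism|AKR1C3|4.88|Dox,Pac",
    "TCGA-BS-A0TE|metabolism|NQO1|3.68|Dox,Pac",
    "TCGA-BS-A0TE|metabolism|NR1I2|2.76|Dox,Pac",
    "TCGA-BS-A0TE|transport|ABCC2|5.22|Top",
    "TCGA-CR-7404|target|MAP2|-3.86|Pac",
    "TCGA-CR-7404|transport|ABCC5|5.08|Cap",
    "TCGA-DQ-7589|transport|ABCC1|5.83|Doc,5FU,Pac",
    "TCGA-DQ-7589|transport|ABCC5|4.74|Doc,5FU,Pac",
    "TCGA-46-6026|metabolism|CMPK1|-3.05|Gem",
    "TCGA-46-6026|metabolism|CYP2C8|3.02|Pac",
    "TCGA-46-6026|metabolism|NR1I2|3.86|Pac",
    "TCGA-94-7033|target|MAP4|-4.71|Doc",
    "TCGA-94-7033|transport|SLC31A1|-3.26|Cis")
  parse <- function(x, cols) {
    df <- as.data.frame(do.call(rbind, strsplit(x, "|", fixed = TRUE)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }
  cases <- parse(cases, c("patient_id", "cancer_type", "age", "stage",
                          "grade", "tem_expected"))
  cases$age <- as.numeric(cases$age)
  cases$stage <- suppressWarnings(as.integer(cases$stage))
  cases$grade <- suppressWarnings(as.integer(cases$grade))
  cases$tem_expected <- cases$tem_expected == "TRUE"
  entries <- parse(entries, c("patient_id", "feature", "gene", "z", "drugs"))
  entries$z <- as.numeric(entries$z)
  list(cases = cases, entries = entries)
}

DRUG_ABBREV <- c(Pac = "paclitaxel", Doc = "docetaxel", Dox = "doxorubicin",
                 Gem = "gemcitabine", `5FU` = "fluorouracil",
                 Meth = "methotrexate", Car = "carboplatin",
                 Carb = "carboplatin", Cis = "cisplatin", Tam = "tamoxifen",
                 Lap = "lapatinib", Top = "topotecan", Cap = "capecitabine")

#' Published patient cases as a frozen rule-engine fixture
#'
#' Returns 24 published cases of aberrant pharmacokinetic or target gene
#' expression likely affecting administered therapies, encoded as inputs
#' for the rule engine: per-patient expression calls built from the
#' reported Z-scores, therapy records for the drugs each reported
#' alteration affects, and the reported evidence itself for comparison.
#' `cases$tem_expected` freezes, per case, whether the therapy-efficacy
#' rule (exporter high, or at least two drug-degrading enzymes high for one
#' drug) should classify some administered therapy as ineffective.
#'
#' @param thr_high,thr_low thresholds used to derive levels from the
#'   reported Z-scores.
#' @return List: `cases` (patient, cancer type, age, stage, grade,
#'   `tem_expected`), `entries` (reported gene/feature/Z/drug evidence,
#'   with generic drug names in `drug_set`), `zcalls` (long-format calls
#'   keyed by patient), `records` (therapy records, one per patient-drug,
#'   start day 0).
#' @export
fixture_published_cases <- function(thr_high = 2, thr_low = -2) {
  d <- published_case_data()
  entries <- d$entries
  entries$drug_set <- vapply(strsplit(entries$drugs, ",", fixed = TRUE),
                             function(a) paste(unname(DRUG_ABBREV[a]),
                                               collapse = ","), character(1))
  zc <- unique(entries[, c("patient_id", "gene", "z")])
  zcalls <- data.frame(sample = zc$patient_id, gene = zc$gene, z = zc$z,
                       stringsAsFactors = FALSE)
  zcalls$level <- call_level(zcalls$z, thr_high, thr_low)
  zcalls$callable <- TRUE
  pd <- unique(data.frame(
    patient_id = rep(entries$patient_id,
                     lengths(strsplit(entries$drug_set, ","))),
    drug = unlist(strsplit(entries$drug_set, ",")),
    stringsAsFactors = FALSE))
  records <- data.frame(patient_id = pd$patient_id, raw_name = pd$drug,
                        start_day = 0L, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(cases = d$cases, entries = entries, zcalls = zcalls, records = records)
}
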