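# Drug-gene pharmacokinetic knowledge base and therapy-name normalization.

#' Pharmacokinetic roles recognised by the knowledge base
#'
#' A drug-gene relationship is typed by the role the gene plays in the drug's
#' pharmacokinetics or mechanism: `import` (influx transporter bringing the
#' drug into the cell), `export` (efflux transporter pumping it out),
#' `metabolize` (enzyme degrading the active drug), `activate` (enzyme
#' converting a prodrug to its active form), and `target` (the protein the
#' drug acts on).
#'
#' @export
PK_ROLES <- c("import", "export", "metabolize", "activate", "target")

fold_name <- function(x) tolower(trimws(x))

#' Build a drug-gene knowledge base from a data frame
#'
#' @param relations data frame with columns `drug`, `gene`, `role` and
#'   optionally `evidence`. Drug names are folded to lower case; gene symbols
#'   are kept as given (HGNC-style upper case expected). Duplicate
#'   (drug, gene, role) triples are collapsed with a warning.
#' @return An object of class `pk_kb`.
#' @export
as_pk_kb <- function(relations) {
  req <- c("drug", "gene", "role")
  if (!all(req %in% names(relations)))
    stop("knowledge base needs columns drug, gene, role", call. = FALSE)
  rel <- data.frame(
    drug = fold_name(as.character(relations$drug)),
    gene = trimws(as.character(relations$gene)),
    role = fold_name(as.character(relations$role)),
    evidence = if ("evidence" %in% names(relations))
      as.character(relations$evidence) else NA_character_,
    stringsAsFactors = FALSE
  )
  bad_role <- which(!rel$role %in% PK_ROLES)
  if (length(bad_role))
    stop(sprintf("unknown role '%s' (row %d); must be one of %s",
                 rel$role[bad_role[1]], bad_role[1],
                 paste(PK_ROLES, collapse = ", ")), call. = FALSE)
  empty <- which(!nzchar(rel$drug) | !nzchar(rel$gene))
  if (length(empty))
    stop(sprintf("empty drug or gene symbol (row %d)", empty[1]), call. = FALSE)
  key <- paste(rel$drug, rel$gene, rel$role, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("collapsed %d duplicate drug-gene-role triple(s)",
                    sum(duplicated(key))), call. = FALSE)
    rel <- rel[!duplicated(key), , drop = FALSE]
  }
  rel <- rel[order(rel$drug, rel$role, rel$gene), , drop = FALSE]
  rownames(rel) <- NULL
  structure(list(relations = rel), class = "pk_kb")
}

#' Read a drug-gene knowledge base from CSV
#'
#' The file must be a UTF-8 CSV with header `drug,gene,role[,evidence]` and
#' `role` one of [PK_ROLES]. Errors name the offending file line (header is
#' line 1).
#'
#' @param path path to the CSV file.
#' @return A `pk_kb` object.
#' @export
read_kb <- function(path) {
  if (!file.exists(path)) stop("knowledge base file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("drug", "gene", "role")
  if (!all(req %in% names(raw)))
    stop("malformed knowledge base header in ", path,
         ": need drug,gene,role[,evidence]", call. = FALSE)
  if (nrow(raw)) {
    bad <- which(!fold_name(raw$role) %in% PK_ROLES |
                   !nzchar(trimws(raw$drug)) | !nzchar(trimws(raw$gene)))
    if (length(bad))
      stop(sprintf("malformed knowledge base row at %s line %d (role '%s')",
                   path, bad[1] + 1L, raw$role[bad[1]]), call. = FALSE)
  }
  as_pk_kb(raw)
}

#' Write a knowledge base back to CSV
#'
#' Round-trips with [read_kb()]: re-reading the written file yields an
#' identical relation set.
#'
#' @param kb a `pk_kb` object.
#' @param path output path.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "pk_kb"))
  utils::write.csv(kb$relations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.pk_kb <- function(x, ...) {
  rel <- x$relations
  cat(sprintf("Drug-gene PK knowledge base: %d relations, %d drugs, %d genes\n",
              nrow(rel), length(unique(rel$drug)), length(unique(rel$gene))))
  print(table(rel$role))
  invisible(x)
}

#' Genes annotated to a drug under a given PK role
#'
#' Pure query: repeated calls agree, and the union over all roles equals all
#' genes annotated to the drug. A drug absent from the knowledge base (for
#' example the non-drug token `radiotherapy`) yields an empty set, never an
#' error.
#'
#' @param kb a `pk_kb` object.
#' @param drug generic drug name (case-insensitive).
#' @param role one of [PK_ROLES].
#' @return Sorted character vector of gene symbols (possibly empty).
#' @export
genes_for <- function(kb, drug, role) {
  stopifnot(inherits(kb, "pk_kb"), length(drug) == 1L, length(role) == 1L)
  role <- match.arg(role, PK_ROLES)
  rel <- kb$relations
  sort(unique(rel$gene[rel$drug == fold_name(drug) & rel$role == role]))
}

#' All drugs present in a knowledge base
#' @param kb a `pk_kb` object.
#' @return Sorted character vector of generic drug names.
#' @export
kb_drugs <- function(kb) {
  stopifnot(inherits(kb, "pk_kb"))
  sort(unique(kb$relations$drug))
}

#' Read a therapy-name normalization map
#'
#' Raw therapy names as recorded in clinical treatment tables (brand names,
#' abbreviations, regimen nicknames) are mapped to sets of generic drug
#' names. The file is a two-column TSV `raw_name<TAB>generic1|generic2|...`.
#' Lookup is case- and surrounding-whitespace-insensitive; mapped generic
#' names are folded to lower case. The token `radiotherapy` is a legal
#' mapped value (regimen nicknames can expand to it) that the rule engine
#' later skips.
#'
#' @param path path to the TSV file.
#' @return An object of class `therapy_name_map`.
#' @export
read_name_map <- function(path) {
  if (!file.exists(path)) stop("name map file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("name map must be two-column TSV", call. = FALSE)
  keys <- fold_name(raw[[1]])
  vals <- lapply(strsplit(raw[[2]], "|", fixed = TRUE), fold_name)
  if (anyDuplicated(keys))
    stop("duplicate raw name in map: ", keys[duplicated(keys)][1], call. = FALSE)
  structure(stats::setNames(vals, keys), class = "therapy_name_map")
}

#' @export
print.therapy_name_map <- function(x, ...) {
  cat(sprintf("Therapy name map: %d raw names -> %d generic names\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Normalize a raw therapy name to generic drug names
#'
#' A raw name found in the map returns its mapped generic set. A raw name
#' equal (case-insensitively, after trimming) to a known generic name maps
#' to itself; `generics` defaults to every generic appearing among the map's
#' values, and passing a `pk_kb` widens it to the knowledge base's drugs.
#' Anything else raises an error of condition class
#' `pktem_unknown_therapy` carrying the raw string, so callers can choose to
#' skip or abort.
#'
#' @param raw single raw therapy name.
#' @param map a `therapy_name_map`.
#' @param kb optional `pk_kb`; its drugs are accepted as self-mapping generics.
#' @return Character vector of generic names (and possibly `"radiotherapy"`).
#' @export
normalize_therapy <- function(raw, map, kb = NULL) {
  stopifnot(inherits(map, "therapy_name_map"), length(raw) == 1L)
  key <- fold_name(raw)
  if (key %in% names(map)) return(unique(map[[key]]))
  generics <- unique(unlist(map, use.names = FALSE))
  if (!is.null(kb)) generics <- union(generics, kb_drugs(kb))
  if (key %in% generics) return(key)
  stop(structure(
    class = c("pktem_unknown_therapy", "error", "condition"),
    list(message = paste0("unknown therapy name: '", raw, "'"),
         call = sys.call(-1), raw_name = raw)))
}

#' Paths to the bundled example knowledge base and name map
#'
#' The package ships a small curated knowledge base of well-established
#' chemotherapy pharmacokinetic relationships (ABC-transporter efflux, SLC
#' influx, CYP/UGT and nucleotide-metabolism enzymes, prodrug activation,
#' and drug targets such as tubulin-associated proteins and growth-factor
#' receptors), together with a matching therapy-name map. It is intentionally
#' partial -- a working example and test fixture, not an exhaustive curation
#' -- and the knowledge-base file is first-class user input: analyses of real
#' cohorts should supply their own curated file in the same format.
#'
#' @return File path within the installed package.
#' @export
example_kb_path <- function() {
  system.file("extdata", "pk_kb.csv", package = "pktem", mustWork = TRUE)
}

#' @rdname example_kb_path
#' @export
example_name_map_path <- function() {
  system.file("extdata", "therapy_names.tsv", package = "pktem", mustWork = TRUE)
}
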