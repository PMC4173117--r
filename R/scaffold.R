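# Scaffold grouping: the server-side counterpart of cluster selection in a
# structure-activity workflow. Compound IDs are grouped by identical
# molecular scaffold keys; key extraction is pluggable, so the core is
# chemistry-toolkit-free.

#' Group compound IDs by identical scaffold keys
#'
#' Applies `scaffold_key` to every compound ID and groups compounds whose
#' canonical keys are equal. Scaffold IDs are 1, 2, 3, ... in order of first
#' appearance in the input; within a group, compound order is input order.
#' Compounds whose key is `NA`/`NULL` (e.g. unparsable structures) are not
#' grouped but listed separately.
#'
#' @param compound_ids character vector of compound identifiers.
#' @param scaffold_key function mapping one compound ID to a canonical
#'   scaffold string, or to `NA`/`NULL` when no scaffold can be derived.
#'   Must be deterministic. Typically a closure over a table of
#'   Murcko-scaffold strings (see [murcko_scaffold_keys]).
#' @return An object of class `scaffold_groups`: list with `groups` (each a
#'   list with `scaffold_id` and `compound_ids`) and `unresolved` (IDs
#'   without a key).
#' @examples
#' keys <- c(a = "c1ccccc1", b = "c1ccccc1", c = "C1CC1")
#' group_by_scaffold(c("a", "b", "c"), function(id) keys[[id]])
#' @export
group_by_scaffold <- function(compound_ids, scaffold_key) {
  stopifnot(is.function(scaffold_key))
  compound_ids <- as.character(compound_ids)
  keys <- vapply(compound_ids, function(id) {
    k <- scaffold_key(id)
    if (is.null(k) || length(k) != 1L || is.na(k)) NA_character_ else as.character(k)
  }, character(1L), USE.NAMES = FALSE)
  keyed <- !is.na(keys)
  uk <- unique(keys[keyed])
  groups <- lapply(seq_along(uk), function(i) {
    list(scaffold_id = i,
         compound_ids = compound_ids[keyed & keys == uk[i]])
  })
  structure(list(groups = groups, unresolved = compound_ids[!keyed]),
            class = "scaffold_groups")
}

#' @export
print.scaffold_groups <- function(x, ...) {
  cat(sprintf("<scaffold_groups: %d group(s), %d unresolved>\n",
              length(x$groups), length(x$unresolved)))
  invisible(x)
}

#' Serialize scaffold groups as a JSON array
#'
#' Emits the `[[1, ["id1", "id2"]], [2, ["id3"]], ...]` array shape used to
#' answer a cluster-selection query.
#'
#' @param groups a `scaffold_groups` object.
#' @return JSON string.
#' @export
scaffold_groups_json <- function(groups) {
  stopifnot(inherits(groups, "scaffold_groups"))
  x <- lapply(groups$groups, function(g) {
    list(g$scaffold_id, I(g$compound_ids))
  })
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
}

#' Read an (ID, SMILES) table
#'
#' Two-column delimited table: compound ID, SMILES string.
#'
#' @inheritParams read_data_table
#' @return Named character vector of SMILES, names are compound IDs.
#' @export
read_smiles_table <- function(file = NULL, delimiter = ",", header = FALSE,
                              text = NULL) {
  lines <- split_input_lines(file, text)
  cells <- parse_delimited_lines(lines, delimiter)
  if (ncol(cells) != 2L) stop("a SMILES table must have exactly 2 columns (id, smiles)")
  if (header) cells <- cells[-1L, , drop = FALSE]
  ids <- cells[, 1L]
  dup <- duplicated(ids)
  if (any(dup)) stop(sprintf("duplicate compound ID '%s'", ids[dup][1L]))
  stats::setNames(cells[, 2L], ids)
}

#' Murcko scaffold keys via an external RDKit interpreter
#'
#' Computes canonical Murcko-scaffold SMILES for a set of molecules by
#' invoking a Python interpreter with RDKit available. Molecules that fail
#' to parse (or have no ring system) yield `NA`. This is an optional
#' chemistry backend; [group_by_scaffold] itself never requires it.
#'
#' @param smiles named character vector (names = compound IDs) as returned by
#'   [read_smiles_table].
#' @param python path to the Python interpreter (default `"python"`).
#' @return Named character vector of canonical scaffold SMILES (`NA` on
#'   failure), names preserved.
#' @export
murcko_scaffold_keys <- function(smiles, python = "python") {
  stopifnot(is.character(smiles))
  infile <- tempfile(fileext = ".txt")
  on.exit(unlink(infile), add = TRUE)
  writeLines(unname(smiles), infile)
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "for line in open(sys.argv[1]):",
    "    smi = line.strip()",
    "    try:",
    "        mol = Chem.MolFromSmiles(smi)",
    "        core = MurckoScaffold.GetScaffoldForMol(mol)",
    "        out = Chem.MolToSmiles(core) if core is not None else ''",
    "    except Exception:",
    "        out = ''",
    "    print(out)",
    sep = "\n")
  res <- suppressWarnings(
    system2(python, c("-c", shQuote(script), shQuote(infile)),
            stdout = TRUE, stderr = FALSE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L) {
    stop("the RDKit scaffold backend is unavailable (python call failed)")
  }
  if (length(res) != length(smiles)) {
    stop("the RDKit scaffold backend returned an unexpected number of lines")
  }
  out <- as.character(res)
  out[!nzchar(out)] <- NA_character_
  stats::setNames(out, names(smiles))
}
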