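#' Construct a labeled fingerprint dataset
#'
#' The central container of the package: an ordered set of compounds, a binary
#' substructure fingerprint matrix, a DILI label per compound, and (optionally)
#' a canonical structure key used for duplicate detection between datasets.
#'
#' @param ids Character vector of unique, non-empty compound identifiers.
#' @param X Matrix with one row per compound and one column per fingerprint
#'   bit; every entry must be 0 or 1.
#' @param labels Character vector with values `"positive"`, `"negative"` or
#'   `"unlabeled"`; recycled from `"unlabeled"` when omitted.
#' @param structure_key Optional character vector of canonical structure
#'   strings (e.g. canonical SMILES), `NA` where unknown.
#'
#' @return An object of class `fp_dataset` with elements `ids`, `X`,
#'   `labels`, `structure_key` and `n_bits`.
#' @seealso [read_padel_csv()], [attach_labels()], [merge_deduplicate()]
#' @export
fp_dataset <- function(ids, X, labels = NULL, structure_key = NULL) {
  ids <- as.character(ids)
  if (length(ids) == 0L && is.null(dim(X))) X <- matrix(numeric(0), 0L, 0L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != length(ids)) {
    stop("number of rows of X (", nrow(X), ") does not match number of compound ids (",
         length(ids), ")")
  }
  if (any(!nzchar(ids)) || anyNA(ids)) stop("compound ids must be non-empty strings")
  if (anyDuplicated(ids)) {
    stop("duplicate compound id: ", ids[anyDuplicated(ids)])
  }
  bad <- which(!(X %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(X)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(X)) + 1L
    stop("fingerprint entries must be 0 or 1; offending value ", X[i, j],
         " at row '", ids[i], "', column ", j)
  }
  if (is.null(labels)) labels <- rep("unlabeled", length(ids))
  labels <- as.character(labels)
  if (length(labels) != length(ids)) stop("labels length must match ids")
  ok <- labels %in% c("positive", "negative", "unlabeled")
  if (!all(ok)) stop("invalid label '", labels[!ok][1], "'; must be positive/negative/unlabeled")
  if (!is.null(structure_key)) {
    structure_key <- as.character(structure_key)
    if (length(structure_key) != length(ids)) stop("structure_key length must match ids")
  }
  rownames(X) <- ids
  if (is.null(colnames(X))) colnames(X) <- paste0("PubchemFP", seq_len(ncol(X)) - 1L)
  structure(list(ids = ids, X = X, labels = labels,
                 structure_key = structure_key, n_bits = ncol(X)),
            class = "fp_dataset")
}

#' @export
print.fp_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("positive", "negative", "unlabeled")))
  cat("<fp_dataset> ", length(x$ids), " compounds x ", x$n_bits, " bits (",
      tab[["positive"]], " positive, ", tab[["negative"]], " negative, ",
      tab[["unlabeled"]], " unlabeled)\n", sep = "")
  invisible(x)
}

#' Read a PaDEL-Descriptor fingerprint CSV
#'
#' Parses the CSV dialect written by PaDEL-Descriptor for PubChem fingerprints:
#' a first identifier column (conventionally `Name`) followed by bit columns
#' `PubchemFP0` ... `PubchemFP<n_bits-1>`. All compounds are returned unlabeled;
#' attach labels with [attach_labels()].
#'
#' @param path Path to the CSV file.
#' @param n_bits Expected number of fingerprint columns (default 881, the
#'   length of the PubChem fingerprint).
#' @return An unlabeled [fp_dataset()].
#' @export
read_padel_csv <- function(path, n_bits = 881L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) != n_bits + 1L) {
    stop("expected 1 id column + ", n_bits, " fingerprint columns, found ",
         ncol(df), " columns in ", path)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate compound id in ", path, ": ",
                               ids[anyDuplicated(ids)])
  X <- matrix(0, nrow(df), n_bits, dimnames = list(ids, colnames(df)[-1L]))
  for (j in seq_len(n_bits)) {
    v <- df[[j + 1L]]
    bad <- which(!(v %in% c("0", "1")))
    if (length(bad)) {
      stop("non-binary fingerprint value '", v[bad[1]], "' at row '", ids[bad[1]],
           "', column '", colnames(df)[j + 1L], "' in ", path)
    }
    X[, j] <- as.numeric(v)
  }
  fp_dataset(ids, X)
}

#' Write a dataset in PaDEL-Descriptor CSV dialect
#'
#' @param ds An [fp_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_padel_csv <- function(ds, path) {
  stopifnot(inherits(ds, "fp_dataset"))
  df <- data.frame(Name = ds$ids, ds$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column compound label CSV
#'
#' @param path CSV with header `compound_id,label`, label in
#'   `{positive, negative}`.
#' @return Named character vector of labels keyed by compound id.
#' @export
read_label_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("label file must have columns compound_id,label")
  labels <- df[[2L]]
  ok <- labels %in% c("positive", "negative")
  if (!all(ok)) stop("invalid label '", labels[!ok][1], "' in ", path)
  stats::setNames(labels, df[[1L]])
}

#' Write a two-column compound label CSV
#'
#' Unlabeled compounds are omitted.
#'
#' @param ds An [fp_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_csv <- function(ds, path) {
  keep <- ds$labels != "unlabeled"
  utils::write.csv(data.frame(compound_id = ds$ids[keep], label = ds$labels[keep]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach class labels to a dataset
#'
#' @param ds An [fp_dataset()].
#' @param labels Named character vector (`compound_id -> label`) with labels in
#'   `{positive, negative, unlabeled}`. Every name must occur in `ds`;
#'   compounds not named keep their current label of `"unlabeled"`.
#' @return The dataset with labels applied.
#' @export
attach_labels <- function(ds, labels) {
  stopifnot(inherits(ds, "fp_dataset"))
  if (length(labels) == 0L) return(ds)
  nm <- names(labels)
  if (is.null(nm) || any(!nzchar(nm))) stop("labels must be a named vector keyed by compound id")
  dup <- nm[duplicated(nm)]
  for (d in dup) {
    if (length(unique(labels[nm == d])) > 1L) {
      stop("conflicting label assignment for compound '", d, "'")
    }
  }
  missing <- setdiff(nm, ds$ids)
  if (length(missing)) stop("compound id not in dataset: ", missing[1])
  out <- ds
  idx <- match(nm, ds$ids)
  lab <- as.character(labels)
  ok <- lab %in% c("positive", "negative", "unlabeled")
  if (!all(ok)) stop("invalid label '", lab[!ok][1], "'")
  out$labels[idx] <- lab
  out
}

#' Set canonical structure keys on a dataset
#'
#' @param ds An [fp_dataset()].
#' @param keys Character vector of canonical structure strings, one per
#'   compound (or a named vector keyed by compound id).
#' @return The dataset with `structure_key` set.
#' @export
set_structure_keys <- function(ds, keys) {
  stopifnot(inherits(ds, "fp_dataset"))
  if (!is.null(names(keys))) {
    missing <- setdiff(names(keys), ds$ids)
    if (length(missing)) stop("compound id not in dataset: ", missing[1])
    full <- rep(NA_character_, length(ds$ids))
    full[match(names(keys), ds$ids)] <- as.character(keys)
    keys <- full
  }
  if (length(keys) != length(ds$ids)) stop("keys length must match number of compounds")
  ds$structure_key <- as.character(keys)
  ds
}

#' Canonicalize SMILES strings
#'
#' Compound identity in this package is string equality of canonical SMILES.
#' Canonicalization is delegated to the Open Babel toolkit (via ChemmineOB)
#' when it is installed; otherwise the trimmed input string is returned with a
#' warning, which may miss true duplicates written in different SMILES forms.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical structure keys (`NA` where
#'   canonicalization failed).
#' @export
canonicalize_smiles <- function(smiles) {
  smiles <- trimws(as.character(smiles))
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    warning("ChemmineOB not available; using raw SMILES strings as structure keys")
    return(smiles)
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) NA_character_)
    if (is.na(out)) return(NA_character_)
    key <- strsplit(trimws(out), "[ \t]")[[1]][1]
    if (is.na(key) || !nzchar(key)) NA_character_ else key
  }, character(1), USE.NAMES = FALSE)
}

#' Read a SMILES list file
#'
#' One structure per line, with an optional tab-separated compound identifier
#' in the second column. Lines without an identifier are numbered.
#'
#' @param path Path to the SMILES file.
#' @return Data frame with columns `compound_id` and `smiles`.
#' @export
read_smiles_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  smiles <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L && nzchar(parts[[i]][2L])) parts[[i]][2L]
    else paste0("mol_", i)
  }, character(1))
  data.frame(compound_id = ids, smiles = trimws(smiles))
}

#' Remove train/test duplicates and label contradictions from a test set
#'
#' Prepares an independent test set against a fixed training set: any test
#' compound whose canonical structure key occurs in the training set is
#' dropped, and any structure key carried by both a positive and a negative
#' test record is dropped entirely (both records), since a contradictory label
#' cannot be adjudicated from the data.
#'
#' @param train Training [fp_dataset()]; `structure_key` must be set for all
#'   records.
#' @param other Candidate test [fp_dataset()]; `structure_key` must be set for
#'   all records.
#' @return `other` restricted to records that share no structure with `train`
#'   and carry a single consistent label per structure.
#' @export
merge_deduplicate <- function(train, other) {
  stopifnot(inherits(train, "fp_dataset"), inherits(other, "fp_dataset"))
  for (ds in list(train, other)) {
    if (is.null(ds$structure_key) || anyNA(ds$structure_key)) {
      stop("merge_deduplicate requires structure_key for every record in both datasets")
    }
  }
  keep <- !(other$structure_key %in% train$structure_key)
  lab <- other$labels
  key <- other$structure_key
  for (k in unique(key)) {
    labs <- unique(lab[key == k & lab != "unlabeled"])
    if (all(c("positive", "negative") %in% labs)) keep[key == k] <- FALSE
  }
  subset_fp_dataset(other, keep)
}

# Row subset preserving all parallel fields.
subset_fp_dataset <- function(ds, idx) {
  fp_dataset(ds$ids[idx], ds$X[idx, , drop = FALSE], ds$labels[idx],
             if (!is.null(ds$structure_key)) ds$structure_key[idx])
}
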