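#' Per-bit PubChem fingerprint annotation
#'
#' Returns a category and section description for each of the 881 PubChem
#' fingerprint bits, derived from the section layout of the public PubChem
#' fingerprint specification (element counts, ring systems, atom pairs,
#' neighbor patterns, SMARTS patterns). Per-bit SMARTS text is not shipped;
#' supply a richer `annotation` map to [alert_table()] if you need it.
#'
#' @param n_bits Number of bits (default 881; larger indices get a generic
#'   annotation).
#' @return Data frame with columns `bit_index` (0-based), `category`,
#'   `description`.
#' @export
pubchem_bit_annotation <- function(n_bits = 881L) {
  sections <- utils::read.csv(system.file("extdata", "pubchem_fp_sections.csv",
                                          package = "diliwfp"))
  bit <- seq_len(n_bits) - 1L
  category <- rep("SMARTS pattern", n_bits)
  description <- rep("PubChem fingerprint bit (outside the 881-bit layout)", n_bits)
  for (i in seq_len(nrow(sections))) {
    sel <- bit >= sections$start[i] & bit <= sections$end[i]
    category[sel] <- sections$category[i]
    description[sel] <- paste0(sections$section[i], " (bits ", sections$start[i],
                               "-", sections$end[i], ")")
  }
  data.frame(bit_index = bit, category = category, description = description)
}

#' Structural alert table
#'
#' Lists the substructure bits selected at a log-odds threshold — the
#' candidate structural alerts enriched in DILI-positive compounds — sorted
#' by L descending (ties broken by ascending bit index), with class counts
#' and PubChem bit annotations.
#'
#' @param stats A `substructure_stats` object from [smoothed_stats()].
#' @param theta Selection threshold on L.
#' @param annotation Optional named character vector mapping 0-based bit
#'   indices (as names) to description text; defaults to the packaged section
#'   annotation. Bits without annotation get a placeholder with a warning.
#' @return A data frame of class `alert_table` with columns `bit_index`
#'   (0-based), `L`, `c_SP`, `c_SN`, `category`, `description`.
#' @export
alert_table <- function(stats, theta, annotation = NULL) {
  stopifnot(inherits(stats, "substructure_stats"))
  sel <- which(stats$L >= theta)
  base <- pubchem_bit_annotation(length(stats$L))
  desc <- base$description
  categ <- base$category
  if (!is.null(annotation)) {
    nm <- suppressWarnings(as.integer(names(annotation)))
    if (anyNA(nm)) stop("annotation names must be 0-based bit indices")
    known <- nm >= 0 & nm < length(stats$L)
    desc[nm[known] + 1L] <- as.character(annotation)[known]
    missing <- setdiff(sel - 1L, nm)
    if (length(missing)) {
      warning("no annotation for ", length(missing), " selected bit(s); using the ",
              "packaged section description")
    }
  }
  ord <- sel[order(-stats$L[sel], sel)]
  out <- data.frame(bit_index = ord - 1L, L = stats$L[ord],
                    c_SP = stats$c_SP[ord], c_SN = stats$c_SN[ord],
                    category = categ[ord], description = desc[ord],
                    row.names = NULL)
  class(out) <- c("alert_table", "data.frame")
  out
}

#' Write an alert table as CSV and readable text
#'
#' @param at An [alert_table()].
#' @param csv_path Output CSV path.
#' @param txt_path Optional human-readable text path.
#' @return `csv_path`, invisibly.
#' @export
write_alert_table <- function(at, csv_path, txt_path = NULL) {
  utils::write.csv(at, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    lines <- c(sprintf("%d substructure alert(s)", nrow(at)),
               sprintf("bit %4d  L=%6.3f  pos=%4d neg=%4d  [%s] %s",
                       at$bit_index, at$L, at$c_SP, at$c_SN, at$category,
                       at$description))
    writeLines(lines, txt_path)
  }
  invisible(csv_path)
}

#' Multi-model consensus of positive predictions
#'
#' Summarizes agreement between classifiers run over the same compound batch
#' (e.g. RF and SVM screening of a natural-product library): per-model
#' positive counts, and the sizes of the intersection (compounds every model
#' calls positive — the high-confidence hepatotoxicity candidates) and union.
#'
#' @param predictions Named list of label vectors (`"positive"`/`"negative"`),
#'   all of the same length and compound order.
#' @return An object of class `consensus_summary`: list with `n_total`,
#'   `n_pos_by_model`, `n_pos_intersection`, `n_pos_union`.
#' @export
consensus <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 1)
  lens <- lengths(predictions)
  if (length(unique(lens)) != 1L) {
    stop("prediction lists have differing lengths: ", paste(lens, collapse = ", "))
  }
  if (is.null(names(predictions))) names(predictions) <- paste0("model_", seq_along(predictions))
  pos <- lapply(predictions, function(p) p == "positive")
  structure(list(n_total = lens[[1]],
                 n_pos_by_model = vapply(pos, sum, 0L),
                 n_pos_intersection = sum(Reduce(`&`, pos)),
                 n_pos_union = sum(Reduce(`|`, pos))),
            class = "consensus_summary")
}

#' @export
print.consensus_summary <- function(x, ...) {
  cat("<consensus_summary> n=", x$n_total, "; positives per model: ",
      paste(names(x$n_pos_by_model), x$n_pos_by_model, sep = "=", collapse = ", "),
      "; intersection=", x$n_pos_intersection, ", union=", x$n_pos_union, "\n",
      sep = "")
  invisible(x)
}

#' Write a consensus summary as JSON
#'
#' @param cs A [consensus()] summary.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_consensus_json <- function(cs, path) {
  stopifnot(inherits(cs, "consensus_summary"))
  jsonlite::write_json(list(n_total = cs$n_total,
                            n_pos_by_model = as.list(cs$n_pos_by_model),
                            n_pos_intersection = cs$n_pos_intersection,
                            n_pos_union = cs$n_pos_union),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
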