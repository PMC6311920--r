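#' Parse an isomiR name
#'
#' IsomiR names consist of the parent mature miRNA name and a variant symbol
#' separated by `|`, e.g. `"hsa-miR-21-5p | 3′t-2"`. The variant symbol
#' encodes the modified end (3′ or 5′), the modification type
#' (`t` = trimming, `a` = addition) and the number of nucleotides involved.
#' Both the unicode prime (′) and an ASCII apostrophe are accepted;
#' the canonical form emitted by [format_isomir_id()] uses the unicode prime.
#'
#' @param name A single isomiR name string.
#' @return An object of class `isomir_id`: a list with elements `mirna`
#'   (parent miRNA, case preserved), `end` (`"3p"` or `"5p"` for the
#'   3′/5′ end), `change` (`"trim"` or `"addition"`), `n_nt`
#'   (positive integer count of nucleotides trimmed/added) and `raw`
#'   (the input string).
#' @examples
#' parse_isomir_name("hsa-miR-21-5p | 3't-2")
#' @seealso [format_isomir_id()]
#' @export
parse_isomir_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop_data("isomiR name must be a single string")
  if (!grepl("|", name, fixed = TRUE))
    stop_data("malformed isomiR name '", name, "': missing '|' separator")
  parts <- strsplit(name, "|", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop_data("malformed isomiR name '", name,
              "': expected exactly one '|' separator")
  mirna <- trimws(parts[1L])
  if (!nzchar(mirna))
    stop_data("malformed isomiR name '", name, "': empty miRNA name")
  variant <- trimws(parts[2L])
  m <- regmatches(variant,
                  regexec("^([35])[′'’]([ta])-([0-9]+)$", variant))[[1L]]
  if (length(m) == 0L)
    stop_data("malformed isomiR variant symbol '", variant,
              "': expected {3|5}′{t|a}-<count>")
  n_nt <- as.integer(m[4L])
  if (is.na(n_nt) || n_nt < 1L)
    stop_data("malformed isomiR variant symbol '", variant,
              "': nucleotide count must be a positive integer")
  structure(
    list(mirna = mirna,
         end = if (m[2L] == "3") "3p" else "5p",
         change = if (m[3L] == "t") "trim" else "addition",
         n_nt = n_nt,
         raw = name),
    class = "isomir_id")
}

#' Format an isomiR identifier in canonical form
#'
#' The canonical form is `"<mirna> |<end><code>-<n>"` with the unicode prime,
#' e.g. `"hsa-mir-106b-5p |5′a-1"`. Parsing a canonical name and
#' formatting it again is the identity.
#'
#' @param id An `isomir_id` object from [parse_isomir_name()].
#' @return A single string.
#' @export
format_isomir_id <- function(id) {
  if (!inherits(id, "isomir_id")) stop_data("`id` must be an isomir_id")
  paste0(id$mirna, " |",
         if (id$end == "3p") "3′" else "5′",
         if (id$change == "trim") "t" else "a",
         "-", id$n_nt)
}

#' @export
print.isomir_id <- function(x, ...) {
  cat("<isomir_id> ", format_isomir_id(x), "\n",
      "  parent: ", x$mirna, "\n",
      "  variant: ", x$n_nt, " nt ", x$change, " at the ",
      if (x$end == "3p") "3′" else "5′", " end\n", sep = "")
  invisible(x)
}
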