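#' @keywords internal
"_PACKAGE"

# Session-local counter used for opaque identifiers in random mode; keeps id
# generation off the user-visible RNG stream so seeded simulations are not
# perturbed by ingest.
.id_state <- new.env(parent = emptyenv())
.id_state$counter <- 0L

#' Generate an opaque internal identifier
#'
#' Every persisted record carries an internal id that is independent of the
#' source document.  In random mode ids are unique per session; in
#' deterministic mode they are derived from their components (typically data
#' source, model id, element kind and SBML id) so that repeated ingests of
#' the same document produce identical ids, which keeps fixtures and stores
#' reproducible.
#'
#' @param ... character components the deterministic id is derived from.
#' @param deterministic derive the id from `...` instead of generating a
#'   fresh one.
#' @return a single character id.
#' @export
new_internal_id <- function(..., deterministic = FALSE) {
  parts <- vapply(list(...), as.character, character(1))
  if (deterministic) {
    return(paste(parts, collapse = ":"))
  }
  .id_state$counter <- .id_state$counter + 1L
  sprintf("sb-%s-%06x-%04x",
          format(Sys.time(), "%Y%m%d%H%M%S"),
          .id_state$counter,
          Sys.getpid() %% 65536L)
}

# scalar helpers: xml2 returns NA for missing attributes; the record model
# keeps them as NA (absent), never substituting defaults unless SBML defines
# one.
`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

as_flag <- function(x, default) {
  if (is.na(x)) return(default)
  tolower(x) %in% c("true", "1")
}
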