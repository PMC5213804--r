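#' Export a CPO analysis as a structured JSON report
#'
#' Serialises the configuration (including every seed used), all
#' fractions, pseudo-F statistics and p-values, the selected variables,
#' the variance partition and the triplot score tables.  The file
#' round-trips through [read_report()].
#'
#' @param report a `"cpo_analysis"` object.
#' @param path output file; its directory must exist.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cpo_analysis"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  score_tab <- function(m) {
    if (is.null(m)) {
      return(NULL)
    }
    data.frame(label = rownames(m), as.data.frame(unclass(m)), check.names = FALSE)
  }
  sel_tab <- function(fs) {
    if (is.null(fs)) {
      return(NULL)
    }
    list(
      steps = as.data.frame(fs),
      selected = as.list(attr(fs, "selected")),
      stopped_at = attr(fs, "stopped_at"),
      alpha = attr(fs, "alpha")
    )
  }
  obj <- list(
    schema_version = "1.0",
    config = report$config,
    ecology = list(
      selection = sel_tab(report$ecology$selection),
      marginal = as.data.frame(report$ecology$marginal)
    ),
    cpo = list(
      marginal = as.data.frame(report$cpo$marginal),
      selection = sel_tab(report$cpo$selection)
    ),
    partition = if (is.null(report$partition)) NULL else unclass(report$partition),
    joint = if (is.null(report$joint)) {
      NULL
    } else {
      list(
        fraction = report$joint$fraction,
        F = pseudo_f(report$joint),
        eigenvalues = report$joint$eig,
        df = c(q = report$joint$q, residual = report$joint$df_residual)
      )
    },
    triplot = if (is.null(report$triplot)) {
      NULL
    } else {
      list(
        species_points = score_tab(report$triplot$species_points),
        response_arrows = score_tab(report$triplot$response_arrows),
        constraint_arrows = score_tab(report$triplot$constraint_arrows)
      )
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON file.
#' @return a nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("no such report: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
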