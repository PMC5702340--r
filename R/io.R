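# Delimited-text readers/writers for the pipeline's tabular formats and the
# run manifest.  All tables are comma-separated with a required header;
# concentrations are nM and block is on the 0-100 percent scale throughout.

#' Write a Milnes trace dataset as delimited text
#'
#' Columns: `drug, cell_id, concentration_nM, sweep, time_ms, frac_current`.
#'
#' @param ds A [trace_dataset()].
#' @param path Output file.
#' @export
write_trace_table <- function(ds, path) {
  rows <- lapply(seq_along(ds$traces), function(i) {
    tr <- ds$traces[[i]]
    data.frame(drug = ds$drug, cell_id = ds$cell_id[i],
               concentration_nM = ds$conc[i],
               sweep = rep(seq_len(ncol(tr)), each = nrow(tr)),
               time_ms = rep(ds$time_ms, ncol(tr)),
               frac_current = as.vector(tr))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read a Milnes trace table
#'
#' Validates the format: required columns, a uniform strictly-increasing
#' time grid shared by all sweeps, and one concentration per cell.
#'
#' @param path CSV file as written by [write_trace_table()].
#' @return A [trace_dataset()].
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("drug", "cell_id", "concentration_nM", "sweep", "time_ms",
            "frac_current")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("trace table is missing column(s): ", paste(missing, collapse = ", "))
  per_cell <- tapply(tab$concentration_nM, tab$cell_id,
                     function(x) length(unique(x)))
  bad <- names(per_cell)[per_cell > 1]
  if (length(bad))
    stop("cell(s) listed at more than one concentration: ",
         paste(bad, collapse = ", "))
  cells <- unique(tab$cell_id)
  grid <- sort(unique(tab$time_ms))
  if (any(diff(grid) <= 0)) stop("non-monotone time grid")
  sweeps <- sort(unique(tab$sweep))
  traces <- lapply(cells, function(cid) {
    sub <- tab[tab$cell_id == cid, ]
    m <- matrix(NA_real_, length(grid), length(sweeps))
    for (s in seq_along(sweeps)) {
      ss <- sub[sub$sweep == sweeps[s], ]
      ss <- ss[order(ss$time_ms), ]
      if (!isTRUE(all.equal(ss$time_ms, grid)))
        stop("cell ", cid, " sweep ", sweeps[s],
             " does not share the common time grid")
      m[, s] <- ss$frac_current
    }
    m
  })
  conc <- unname(vapply(cells, function(cid)
    tab$concentration_nM[tab$cell_id == cid][1], numeric(1)))
  trace_dataset(traces, conc, grid, cell_id = as.character(cells),
                drug = tab$drug[1])
}

#' Write dose-response points as delimited text
#'
#' Columns: `drug, current, concentration_nM, block_percent, replicate`.
#'
#' @param points data.frame from [dose_response_points()].
#' @param drug,current Identifiers for the table.
#' @param path Output file.
#' @export
write_doseresponse_table <- function(points, drug, current, path) {
  utils::write.csv(data.frame(drug = drug, current = current,
                              concentration_nM = points$conc,
                              block_percent = points$block,
                              replicate = points$replicate),
                   path, row.names = FALSE)
}

#' Read a dose-response table, grouped by drug and current
#'
#' Unknown current names are rejected against the six-current whitelist;
#' negative concentrations are an error; block outside \[-20, 120\] percent
#' draws a warning (noise can legitimately stray slightly outside \[0, 100\]).
#'
#' @param path CSV file with columns `drug, current, concentration_nM,
#'   block_percent, replicate`.
#' @return Nested named list: `result[[drug]][[current]]` is a
#'   [dose_response_points()] data.frame (possibly zero-row for a null
#'   effect).
#' @export
read_doseresponse_table <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("drug", "current", "concentration_nM", "block_percent",
            "replicate")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("dose-response table is missing column(s): ",
         paste(missing, collapse = ", "))
  valid <- c("ICaL", "INaL", "INa", "Ito", "IKs", "IK1")
  bad <- setdiff(unique(tab$current), valid)
  if (length(bad))
    stop("unknown current name(s): ", paste(bad, collapse = ", "))
  if (any(tab$concentration_nM <= 0)) stop("non-positive concentration")
  if (any(tab$block_percent < -20 | tab$block_percent > 120))
    warning("block values outside [-20, 120] percent")
  out <- list()
  for (d in unique(tab$drug)) {
    out[[d]] <- list()
    for (cn in unique(tab$current[tab$drug == d])) {
      sub <- tab[tab$drug == d & tab$current == cn, ]
      out[[d]][[cn]] <- dose_response_points(sub$concentration_nM,
                                             sub$block_percent,
                                             sub$replicate)
    }
  }
  out
}

#' Write an MCMC chain as delimited text
#' @param chain An [mcmc_hill()] chain.
#' @param path Output file (columns `draw, pIC50, h, sigma2`).
#' @export
write_chain <- function(chain, path) {
  utils::write.csv(data.frame(draw = seq_len(nrow(chain$draws)),
                              pIC50 = chain$draws[, "pIC50"],
                              h = chain$draws[, "h"],
                              sigma2 = chain$sigma2),
                   path, row.names = FALSE)
}

#' Read an MCMC chain written by [write_chain()]
#' @param path CSV file.
#' @return An `mcmc_chain`.
#' @export
read_chain <- function(path) {
  tab <- utils::read.csv(path)
  structure(list(draws = cbind(pIC50 = tab$pIC50, h = tab$h),
                 sigma2 = tab$sigma2, acceptance = NA_real_,
                 seed = NA_integer_, n_saved = nrow(tab)),
            class = "mcmc_chain")
}

#' Write a run manifest
#'
#' Records command, seeds, package version, input checksums and a timestamp
#' alongside pipeline outputs, for reproducibility.
#'
#' @param dir Output directory (one manifest per directory).
#' @param command Command or function name.
#' @param seed Seed(s) used.
#' @param inputs Character vector of input file paths (checksummed).
#' @param extra Optional named list of additional fields.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, seed, inputs = character(),
                           extra = list()) {
  manifest <- c(list(
    command = command,
    seed = seed,
    package = "qnetuq",
    version = as.character(utils::packageVersion("qnetuq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(stats::setNames(nm = inputs), function(f)
      unname(tools::md5sum(f)))), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
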