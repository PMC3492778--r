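## Readers and writers for the package's plain-text interchange formats.

## "#key=value" metadata lines at the top of a CSV.
.readMeta <- function(lines) {
    metaLines <- grep("^#", lines, value = TRUE)
    kv <- sub("^#", "", metaLines)
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(as.list(vals), keys)
}

#' Read a mate-choice contingency table from CSV
#'
#' Two layouts are accepted.  The long layout has header
#' \code{design,strain_female,strain_male,count} and one row per cell; the
#' compact layout mirrors the canonical 2x2 block (rows AA,AB then BA,BB,
#' female strain first) and declares \code{#design=} and \code{#strains=}
#' in metadata lines.  Both accept \code{#replicates=} and
#' \code{#no_mating=} metadata.  The loader enforces all
#' \linkS4class{MatingTable} invariants, including that matings plus
#' non-mating trials never exceed the replicate count.
#'
#' @param path file path (UTF-8).
#' @return a \linkS4class{MatingTable}.
#' @export
readMatingCSV <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("parse error: '", path, "' is empty")
    meta <- .readMeta(lines)
    body <- grep("^#", lines, invert = TRUE, value = TRUE)
    if (!length(body)) stop("parse error: '", path, "' has no data rows")
    nRep <- as.integer(meta$replicates %||% 0L)
    nNo <- if (!is.null(meta$no_mating)) as.integer(meta$no_mating) else NULL

    if (grepl("^design", body[1L])) {                       # long layout
        d <- utils::read.csv(text = body, stringsAsFactors = FALSE)
        need <- c("design", "strain_female", "strain_male", "count")
        if (!all(need %in% names(d)))
            stop("parse error: expected columns ", paste(need, collapse = ", "))
        bad <- which(is.na(suppressWarnings(as.numeric(d$count))))
        if (length(bad))
            stop("parse error at data line ", bad[1L] + 1L,
                 ": count is not numeric")
        design <- unique(d$design)
        if (length(design) != 1L)
            stop("validation error: mixed designs in one table")
        strains <- unique(c(d$strain_female, d$strain_male))
        if (length(strains) != 2L)
            stop("validation error: expected exactly two strains, got ",
                 length(strains))
        cnt <- matrix(0, 2L, 2L, dimnames = list(strains, strains))
        for (r in seq_len(nrow(d)))
            cnt[d$strain_female[r], d$strain_male[r]] <- d$count[r]
    } else {                                                # compact layout
        if (is.null(meta$design) || is.null(meta$strains))
            stop("parse error: compact layout needs #design= and #strains=")
        design <- meta$design
        strains <- trimws(strsplit(meta$strains, ",")[[1L]])
        rows <- lapply(body, function(l) {
            v <- suppressWarnings(as.numeric(strsplit(l, ",")[[1L]]))
            if (length(v) != 2L || anyNA(v))
                stop("parse error: malformed compact row '", l, "'")
            v
        })
        if (length(rows) != 2L)
            stop("parse error: compact layout needs exactly two rows")
        cnt <- matrix(c(rows[[1L]], rows[[2L]]), 2L, 2L, byrow = TRUE,
                      dimnames = list(strains, strains))
    }
    if (is.null(nNo))
        nNo <- if (nRep > 0L) max(0L, nRep - as.integer(sum(cnt))) else 0L
    new("MatingTable", design = design,
        counts = `dimnames<-`(cnt, list(female = rownames(cnt),
                                        male = colnames(cnt))),
        nReplicates = nRep, nNoMating = as.integer(nNo))
}

#' Write a mate-choice table to CSV (long layout)
#'
#' @param x a \linkS4class{MatingTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMatingCSV <- function(x, path) {
    s <- strainLabels(x)
    cells <- expand.grid(strain_female = s, strain_male = s,
                         stringsAsFactors = FALSE)
    d <- data.frame(design = designType(x), cells,
                    count = matingCounts(x)[cbind(cells$strain_female,
                                                  cells$strain_male)])
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(paste0("#replicates=", nReplicates(x)),
                 paste0("#no_mating=", nNoMating(x))), con)
    utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read no-choice latency data
#'
#' CSV with columns \code{pair_type,latency_min}; the female strain is
#' listed first within each pair-type label.
#'
#' @param path file path.
#' @return data.frame suitable for \code{\link{compareLatencies}}.
#' @export
readLatencyCSV <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("pair_type", "latency_min") %in% names(d)))
        stop("parse error: expected columns pair_type, latency_min")
    if (any(d$latency_min < 0))
        stop("validation error: negative latency")
    d
}

#' Read a per-fly peak-area table
#'
#' CSV with one row per fly: the panel hydrocarbon columns plus
#' \code{std_area}, \code{sex}, \code{strain}, \code{temperature_C}.
#' Column names are matched against the declared panel exactly; unknown
#' hydrocarbon columns are rejected.
#'
#' @param path file path.
#' @param panel data.frame with columns \code{name}, \code{class} (e.g. from
#'   \code{\link{readPanelYAML}}); NULL accepts all non-metadata columns.
#' @param stdMassNg internal-standard mass (ng).
#' @return a \linkS4class{PeakTable}.
#' @export
readPeakCSV <- function(path, panel = NULL, stdMassNg = 500) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    metaCols <- c("fly_id", "sex", "strain", "temperature_C", "std_area")
    need <- setdiff(metaCols, "fly_id")
    if (!all(need %in% names(d)))
        stop("parse error: expected columns ", paste(need, collapse = ", "))
    hcCols <- setdiff(names(d), metaCols)
    areas <- t(as.matrix(d[, hcCols, drop = FALSE]))
    colnames(areas) <- if ("fly_id" %in% names(d)) d$fly_id else
        paste0("fly", seq_len(nrow(d)))
    PeakTable(areas, d[, need], panel = panel, stdMassNg = stdMassNg)
}

#' Read a hydrocarbon panel declaration
#'
#' YAML listing the panel in canonical order, each entry with \code{name}
#' and \code{class} (unsaturated / methylated / linear).
#'
#' @param path YAML file.
#' @return data.frame with columns \code{name}, \code{class}.
#' @export
readPanelYAML <- function(path) {
    y <- yaml::read_yaml(path)
    do.call(rbind, lapply(y$panel, function(e)
        data.frame(name = e$name, class = e$class)))
}

#' Read a gridded desiccation record
#'
#' CSV with columns \code{group,interval_index,deaths} and metadata lines
#' \code{#n0=} and \code{#interval_h=}.
#'
#' @param path file path.
#' @return a \linkS4class{SurvivalRecord}.
#' @export
readDesiccationCSV <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    meta <- .readMeta(lines)
    if (is.null(meta$n0) || is.null(meta$interval_h))
        stop("parse error: need #n0= and #interval_h= metadata")
    d <- utils::read.csv(text = grep("^#", lines, invert = TRUE, value = TRUE),
                         stringsAsFactors = FALSE)
    d <- d[order(d$interval_index), ]
    deaths <- integer(max(d$interval_index))
    deaths[d$interval_index] <- d$deaths
    new("SurvivalRecord", group = as.character(d$group[1L]),
        n0 = as.integer(meta$n0), intervalH = as.numeric(meta$interval_h),
        deaths = deaths)
}

#' @rdname readDesiccationCSV
#' @param x a \linkS4class{SurvivalRecord}.
#' @param path output file.
#' @export
writeDesiccationCSV <- function(x, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(paste0("#n0=", x@n0), paste0("#interval_h=", x@intervalH)), con)
    utils::write.csv(data.frame(group = x@group,
                                interval_index = seq_along(x@deaths),
                                deaths = x@deaths),
                     con, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write / read an isolation result as JSON
#'
#' The JSON carries every estimate with full provenance: coefficient
#' matrices, point estimate, bootstrap SD and p, expected model, bootstrap
#' size, seed, and the package version.
#'
#' @param x an \linkS4class{IsolationResult}.
#' @param path file path.
#' @return \code{writeIsolationJSON}: \code{path}, invisibly;
#'   \code{readIsolationJSON}: the reconstructed
#'   \linkS4class{IsolationResult}.
#' @export
writeIsolationJSON <- function(x, path) {
    out <- list(package = "isopair",
                version = as.character(utils::packageVersion("isopair")),
                design = x@design, strains = x@strains,
                expected_model = x@expectedModel,
                psi = x@psi, pti = x@pti, ipsi = x@ipsi,
                ipsi_sd = x@ipsiSD, p_value = x@pValue,
                n_boot = x@nBoot, seed = x@seed)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    invisible(path)
}

#' @rdname writeIsolationJSON
#' @export
readIsolationJSON <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    dn <- list(female = j$strains, male = j$strains)
    asMat <- function(m) {          # row-major JSON comes back row-per-row
        m <- if (is.matrix(m)) m else do.call(rbind, lapply(m, unlist))
        dimnames(m) <- dn
        m
    }
    new("IsolationResult",
        psi = asMat(j$psi),
        pti = asMat(j$pti),
        ipsi = j$ipsi, ipsiSD = j$ipsi_sd, pValue = j$p_value,
        nBoot = as.integer(j$n_boot), seed = as.integer(j$seed),
        expectedModel = j$expected_model, design = j$design,
        strains = j$strains)
}

#' Tabular report over a set of isolation results
#'
#' One row per result, mirroring the layout of a pairwise mate-choice
#' summary table: strain pair, design, I_PSI +/- SD, p-value, model and
#' bootstrap provenance.
#'
#' @param results list of \linkS4class{IsolationResult}.
#' @param path optional TSV output path.
#' @return the report data.frame (invisibly if written to \code{path}).
#' @export
isolationReport <- function(results, path = NULL) {
    rep <- do.call(rbind, lapply(results, function(r)
        data.frame(strain_pair = paste(r@strains, collapse = "/"),
                   design = r@design, ipsi = r@ipsi, ipsi_sd = r@ipsiSD,
                   p_value = r@pValue, expected_model = r@expectedModel,
                   n_boot = r@nBoot, seed = r@seed)))
    if (!is.null(path)) {
        utils::write.table(rep, path, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        return(invisible(rep))
    }
    rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
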