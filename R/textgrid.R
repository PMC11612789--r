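# Praat TextGrid interval-tier I/O (long and short text dialects) plus the
# equivalent CSV encoding used for behavior annotations.

#' Ethogram categories coded during confrontation experiments
#'
#' The seven dyadic behavior categories: avoidance, box, caravanning,
#' combination (caravanning plus socio-negative in one state event),
#' socio-negative interactions, wire-mesh contact, and proximity with no
#' physical interaction.
#'
#' @return character vector of category names.
#' @export
ethogram_categories <- function() ETHOGRAM

#' Write behavior events as a Praat TextGrid
#'
#' Writes a long-format TextGrid with a single interval tier named
#' `"behavior"`. Gaps between events become empty-label intervals so the tier
#' tiles `[xmin, xmax]` as Praat requires.
#'
#' @param events tibble with `category`, `onset`, `offset` (seconds). Only
#'   interaction-tier events should be written to one tier; overlapping
#'   events are rejected.
#' @param path output file.
#' @param tier tier name.
#' @param xmin,xmax tier limits in seconds; `xmax` defaults to the last
#'   offset.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(events, path, tier = "behavior", xmin = 0,
                           xmax = NULL) {
  ev <- events[order(events$onset), , drop = FALSE]
  if ("tier" %in% names(ev)) ev <- ev[ev$tier == "interaction", , drop = FALSE]
  if (nrow(ev) > 1 && any(ev$onset[-1] < utils::head(ev$offset, -1) - 1e-9)) {
    stop("overlapping events cannot be written to one interval tier")
  }
  xmax <- xmax %||% max(ev$offset, xmin)
  # tile with empty intervals
  xs <- xmin; labs <- character(); xmins <- numeric(); xmaxs <- numeric()
  for (i in seq_len(nrow(ev))) {
    if (ev$onset[i] > xs + 1e-9) {
      xmins <- c(xmins, xs); xmaxs <- c(xmaxs, ev$onset[i]); labs <- c(labs, "")
    }
    xmins <- c(xmins, ev$onset[i]); xmaxs <- c(xmaxs, ev$offset[i])
    labs <- c(labs, ev$category[i])
    xs <- ev$offset[i]
  }
  if (xmax > xs + 1e-9) {
    xmins <- c(xmins, xs); xmaxs <- c(xmaxs, xmax); labs <- c(labs, "")
  }
  num <- function(x) formatC(x, format = "f", digits = 6)
  lines <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    paste0("xmin = ", num(xmin)), paste0("xmax = ", num(xmax)),
    "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
    '        class = "IntervalTier"', paste0('        name = "', tier, '"'),
    paste0("        xmin = ", num(xmin)), paste0("        xmax = ", num(xmax)),
    paste0("        intervals: size = ", length(labs)))
  for (i in seq_along(labs)) {
    lines <- c(lines,
      paste0("        intervals [", i, "]:"),
      paste0("            xmin = ", num(xmins[i])),
      paste0("            xmax = ", num(xmaxs[i])),
      paste0('            text = "', labs[i], '"'))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read interval tiers from a Praat TextGrid
#'
#' Parses both the long (`xmin = ...`) and short text dialects. Only interval
#' tiers are returned; point tiers are skipped.
#'
#' @param path TextGrid file.
#' @return tibble with `tier`, `onset`, `offset`, `label`.
#' @export
read_textgrid <- function(path) {
  if (!file.exists(path)) stop("TextGrid not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 5 || !grepl("ooTextFile", raw[1])) {
    stop("malformed TextGrid (missing ooTextFile header): ", path)
  }
  if (any(grepl("xmin *=", raw))) read_textgrid_long(raw, path)
  else read_textgrid_short(raw, path)
}

read_textgrid_long <- function(raw, path) {
  val <- function(line) as.numeric(sub(".*= *", "", line))
  txt <- function(line) {
    m <- regmatches(line, regexpr('"[^"]*"', line))
    if (length(m) == 0) stop("malformed TextGrid line: ", line)
    gsub('"', "", m)
  }
  out <- list(); tier_name <- NULL; cur <- NULL; is_interval <- FALSE
  i <- 1
  while (i <= length(raw)) {
    line <- raw[i]
    if (grepl("class *=", line)) {
      is_interval <- grepl("IntervalTier", line)
    } else if (grepl("name *=", line)) {
      tier_name <- txt(line)
    } else if (is_interval && grepl("intervals *\\[", line)) {
      xmin <- val(raw[i + 1]); xmax <- val(raw[i + 2]); label <- txt(raw[i + 3])
      if (!is.finite(xmin) || !is.finite(xmax)) {
        stop("malformed interval near line ", i, " in ", path)
      }
      out[[length(out) + 1]] <- tibble::tibble(
        tier = tier_name, onset = xmin, offset = xmax, label = label)
      i <- i + 3
    }
    i <- i + 1
  }
  if (length(out) == 0) stop("no interval tiers found in ", path)
  dplyr::bind_rows(out)
}

read_textgrid_short <- function(raw, path) {
  body <- raw[-(1:2)]
  body <- body[nzchar(trimws(body))]
  # short format: xmin xmax <exists> ntier {class name xmin xmax n {...}}
  ptr <- 3
  ntier <- as.integer(body[ptr + 1])
  ptr <- ptr + 2
  out <- list()
  for (k in seq_len(ntier)) {
    cls <- gsub('"', "", body[ptr]); nm <- gsub('"', "", body[ptr + 1])
    nint <- as.integer(body[ptr + 4])
    ptr <- ptr + 5
    if (grepl("IntervalTier", cls)) {
      for (j in seq_len(nint)) {
        out[[length(out) + 1]] <- tibble::tibble(
          tier = nm, onset = as.numeric(body[ptr]),
          offset = as.numeric(body[ptr + 1]),
          label = gsub('"', "", body[ptr + 2]))
        ptr <- ptr + 3
      }
    } else {
      ptr <- ptr + 2 * nint   # point tier: time + label
    }
  }
  if (length(out) == 0) stop("no interval tiers found in ", path)
  res <- dplyr::bind_rows(out)
  if (any(!is.finite(res$onset)) || any(!is.finite(res$offset))) {
    stop("malformed short TextGrid: ", path)
  }
  res
}

#' Read behavior annotations from TextGrid or CSV
#'
#' Accepts a Praat TextGrid (tier named `"behavior"`, empty labels dropped)
#' or a CSV with columns `category`, `onset`, `offset` and optionally
#' `experiment_id` and `phase`. Categories are validated against the
#' ethogram; unknown categories are rejected naming the offender and its
#' position.
#'
#' @param path annotation file.
#' @param dialect `"auto"` (by extension), `"textgrid"` or `"csv"`.
#' @param experiment_id attached to TextGrid events (one file per
#'   experiment).
#' @return tibble of behavior events (`experiment_id`, `category`, `onset`,
#'   `offset`, `phase` when known).
#' @export
read_annotations <- function(path, dialect = c("auto", "textgrid", "csv"),
                             experiment_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.textgrid$", tolower(path))) "textgrid" else "csv"
  }
  if (dialect == "textgrid") {
    tg <- read_textgrid(path)
    tg <- tg[tg$tier == "behavior" & nzchar(tg$label), , drop = FALSE]
    ev <- tibble::tibble(experiment_id = experiment_id,
                         category = tg$label,
                         onset = tg$onset, offset = tg$offset)
  } else {
    ev <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("category", "onset", "offset") %in% names(ev))) {
      stop("annotation CSV must have columns category, onset, offset: ", path)
    }
    if (!"experiment_id" %in% names(ev)) ev$experiment_id <- experiment_id
    ev <- tibble::as_tibble(ev)
  }
  bad <- which(!ev$category %in% ethogram_categories())
  if (length(bad) > 0) {
    stop("unknown behavior category \"", ev$category[bad[1]],
         "\" at interval ", bad[1], " in ", path)
  }
  if (any(ev$offset <= ev$onset)) {
    stop("behavior event with offset <= onset in ", path)
  }
  ev
}
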