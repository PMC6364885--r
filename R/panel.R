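#' Column dialect for long-format area-harvested panels
#'
#' FAOSTAT-style extracts are long tables with one row per
#' region-year-commodity-element; only one element (by default
#' `"Area harvested"`, in hectares) is retained as the abundance proxy.
#' A dialect names the columns carrying each field and the element to keep.
#'
#' @param region,year,item,element,value column names in the input file.
#' @param keep_element value of the element column to retain; rows with any
#'   other element are dropped. `NULL` keeps all rows (for files already
#'   restricted to one element and lacking an element column).
#' @param sep field separator; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @return a named list of class `"panel_dialect"`.
#' @export
panel_dialect <- function(region = "region", year = "year", item = "item",
                          element = "element", value = "value",
                          keep_element = "Area harvested", sep = NULL) {
  structure(list(region = region, year = year, item = item,
                 element = element, value = value,
                 keep_element = keep_element, sep = sep),
            class = "panel_dialect")
}

#' Read a panel dialect from a key-value config file
#'
#' Each non-blank, non-comment line is `key = value` (or `key: value`) with
#' keys among region, year, item, element, value, keep_element, sep.
#'
#' @param path path to the config file.
#' @return a `"panel_dialect"`.
#' @export
read_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("unparseable dialect line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  allowed <- c("region", "year", "item", "element", "value",
               "keep_element", "sep")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown dialect key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  if (!is.null(args$sep) && args$sep == "\\t") args$sep <- "\t"
  do.call(panel_dialect, args)
}

new_crop_panel <- function(df) {
  df <- df[order(df$region, df$year, df$group, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("crop_panel", "data.frame")
  df
}

validate_panel <- function(df) {
  if (any(is.na(df$area) | df$area < 0))
    stop("validation error: negative or missing area harvested")
  key <- paste(df$region, df$year, df$group, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("validation error: duplicate (region, year, group) rows: ",
         paste(gsub("\r", " / ", utils::head(dup, 5L)), collapse = "; "))
  }
  invisible(df)
}

#' Read an area-harvested panel
#'
#' Reads a delimited long-format file, keeps the dialect's element (e.g.
#' "Area harvested"), trims whitespace from labels, and validates the result.
#' Zero-valued rows are kept as explicit absences (a group observed with zero
#' hectares); missing rows are implicit absences. Duplicate
#' (region, year, group) rows and negative areas are errors.
#'
#' @param path delimited text file (comma or tab separated).
#' @param dialect a [panel_dialect()].
#' @return a `crop_panel`: a data frame with columns `region`, `year`
#'   (integer), `group`, `area` (hectares), one row per record.
#' @export
read_panel <- function(path, dialect = panel_dialect()) {
  sep <- dialect$sep
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  need <- c(region = dialect$region, year = dialect$year,
            item = dialect$item, value = dialect$value)
  if (!is.null(dialect$keep_element))
    need <- c(need, element = dialect$element)
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.null(dialect$keep_element))
    raw <- raw[trimws(raw[[dialect$element]]) == dialect$keep_element, ,
               drop = FALSE]
  yr <- raw[[dialect$year]]
  if (!is.numeric(yr)) {
    yr <- suppressWarnings(as.numeric(trimws(as.character(yr))))
    if (anyNA(yr)) stop("schema error: non-numeric year values")
  }
  df <- data.frame(region = trimws(as.character(raw[[dialect$region]])),
                   year = as.integer(yr),
                   group = trimws(as.character(raw[[dialect$item]])),
                   area = as.numeric(raw[[dialect$value]]),
                   stringsAsFactors = FALSE)
  df$area[is.na(df$area)] <- 0
  validate_panel(df)
  new_crop_panel(df)
}

#' Assemble a panel from an in-memory data frame
#'
#' @param df data frame with columns `region`, `year`, `group`, `area`.
#' @return a validated `crop_panel`.
#' @export
as_crop_panel <- function(df) {
  stopifnot(all(c("region", "year", "group", "area") %in% names(df)))
  df <- data.frame(region = trimws(as.character(df$region)),
                   year = as.integer(df$year),
                   group = trimws(as.character(df$group)),
                   area = as.numeric(df$area),
                   stringsAsFactors = FALSE)
  validate_panel(df)
  new_crop_panel(df)
}

panel_has <- function(panel, region, year) {
  any(panel$region == region & panel$year == year)
}

#' Community vector for one region-year
#'
#' Returns the commodity groups present (area harvested > 0) in the given
#' region and year, as a named abundance vector ordered lexicographically by
#' group label. A region-year that exists in the panel but has no positive
#' areas yields an empty (length-0) community; a region-year absent from the
#' panel is a lookup error, so truncated series (e.g. a region reporting only
#' from 1992) are distinguishable from empty ones.
#'
#' @param panel a `crop_panel`.
#' @param region,year the sample key.
#' @return named numeric vector of areas (ha), names = group labels.
#' @export
community <- function(panel, region, year) {
  sel <- panel$region == region & panel$year == year
  if (!any(sel))
    stop("lookup error: no records for region '", region, "' in year ", year)
  sub <- panel[sel & panel$area > 0, , drop = FALSE]
  x <- sub$area
  names(x) <- sub$group
  x[order(names(x), method = "radix")]
}

#' Net change in the number of commodity groups present
#'
#' Count of groups present in the last year minus the count present in the
#' first year, for one region; negative when groups were lost.
#'
#' @param panel a `crop_panel`.
#' @param region region label.
#' @param first,last calendar years, both present for the region.
#' @return integer net change.
#' @export
net_group_change <- function(panel, region, first, last) {
  n1 <- length(community(panel, region, first))
  n2 <- length(community(panel, region, last))
  as.integer(n2 - n1)
}

#' Years covered by a region in a panel
#' @param panel a `crop_panel`.
#' @param region region label.
#' @return sorted integer years with at least one record.
#' @export
panel_years <- function(panel, region) {
  sort(unique(panel$year[panel$region == region]))
}

#' Region labels in a panel
#' @param panel a `crop_panel`.
#' @return sorted region labels.
#' @export
panel_regions <- function(panel) {
  sort(unique(panel$region), method = "radix")
}

#' Wide region-year x group abundance matrix
#'
#' Canonical audit form: one row per region-year (regions in lexical order,
#' years ascending within region), one column per group (lexical order),
#' entries in hectares with 0 for absence. Empty region-years are kept as
#' all-zero rows.
#'
#' @param panel a `crop_panel`.
#' @return numeric matrix with rownames `"region|year"` and attributes
#'   `region` and `year` giving the row keys.
#' @export
panel_matrix <- function(panel) {
  regions <- panel_regions(panel)
  keys <- do.call(rbind, lapply(regions, function(r)
    data.frame(region = r, year = panel_years(panel, r),
               stringsAsFactors = FALSE)))
  groups <- sort(unique(panel$group), method = "radix")
  m <- matrix(0, nrow = nrow(keys), ncol = length(groups),
              dimnames = list(paste(keys$region, keys$year, sep = "|"),
                              groups))
  i <- match(paste(panel$region, panel$year, sep = "|"), rownames(m))
  j <- match(panel$group, groups)
  m[cbind(i, j)] <- panel$area
  attr(m, "region") <- keys$region
  attr(m, "year") <- keys$year
  m
}

#' Write the wide abundance matrix as tab-delimited text
#' @param panel a `crop_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_matrix <- function(panel, path) {
  m <- panel_matrix(panel)
  df <- data.frame(region = attr(m, "region"), year = attr(m, "year"),
                   as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a commodity-group to species mapping table
#'
#' Two-column delimited text (`group`, `species`), one row per species, in
#' the style of a commodity-list lookup: each commodity group maps to one or
#' more crop species. Species must be unique within a group.
#'
#' @param path delimited file with a header naming columns `group` and
#'   `species` (comma or tab separated).
#' @return named list: group label -> character vector of species labels.
#' @export
read_group_map <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("group", "species") %in% names(df)))
    stop("schema error: mapping file needs columns 'group' and 'species'")
  as_group_map(df$group, df$species)
}

#' Build a group-species map from parallel vectors
#' @param group,species parallel character vectors.
#' @return named list: group -> species labels.
#' @export
as_group_map <- function(group, species) {
  group <- trimws(as.character(group))
  species <- trimws(as.character(species))
  map <- split(species, group)
  dup <- vapply(map, anyDuplicated, 0L) > 0L
  if (any(dup))
    stop("validation error: duplicate species within group(s): ",
         paste(names(map)[dup], collapse = ", "))
  map[order(names(map), method = "radix")]
}

#' Check that a mapping covers every group in a panel
#' @param map a group-species map.
#' @param panel a `crop_panel`.
#' @return invisibly `TRUE`; errors listing uncovered groups otherwise.
#' @export
check_group_map <- function(map, panel) {
  missing <- setdiff(unique(panel$group), names(map))
  if (length(missing))
    stop("validation error: groups missing from mapping: ",
         paste(sort(missing), collapse = ", "))
  invisible(TRUE)
}
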