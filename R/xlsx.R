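# Minimal built-in XLSX writer.
#
# An .xlsx workbook is a ZIP archive of XML parts. Entries are stored
# uncompressed (method 0), which keeps the container trivial and the output
# deterministic; CRC-32 comes from digest. Strings are written as inline
# strings so no shared-string table is needed. Four cell styles: default,
# bold header, red fill (identity flag), amber fill (coverage/tag flag).

int_le <- function(x, width) {
  as.raw((x %/% 256^(0:(width - 1))) %% 256)
}

crc32_value <- function(bytes) {
  hex <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  hex <- formatC(hex, width = 8, flag = "0")
  sum(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L) * 256^(3:0))
}

# store-only ZIP archive; `files` is a named list of raw vectors
zip_store <- function(files, path) {
  dos_time <- 0          # 00:00:00
  dos_date <- bitwOr(bitwOr(bitwShiftL(2024L - 1980L, 9L), bitwShiftL(1L, 5L)), 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  central <- list()
  offset <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    crc <- crc32_value(data)
    local <- c(
      int_le(0x04034b50, 4), int_le(20, 2), int_le(0, 2), int_le(0, 2),
      int_le(dos_time, 2), int_le(dos_date, 2), int_le(crc, 4),
      int_le(length(data), 4), int_le(length(data), 4),
      int_le(length(name), 2), int_le(0, 2), name
    )
    offsets[i] <- offset
    writeBin(c(local, data), con)
    offset <- offset + length(local) + length(data)
    central[[i]] <- c(
      int_le(0x02014b50, 4), int_le(20, 2), int_le(20, 2), int_le(0, 2),
      int_le(0, 2), int_le(dos_time, 2), int_le(dos_date, 2), int_le(crc, 4),
      int_le(length(data), 4), int_le(length(data), 4),
      int_le(length(name), 2), int_le(0, 2), int_le(0, 2), int_le(0, 2),
      int_le(0, 2), int_le(0, 4), int_le(offsets[i], 4), name
    )
  }
  cd <- unlist(central)
  writeBin(cd, con)
  eocd <- c(
    int_le(0x06054b50, 4), int_le(0, 2), int_le(0, 2),
    int_le(length(files), 2), int_le(length(files), 2),
    int_le(length(cd), 4), int_le(offset, 4), int_le(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

col_ref <- function(j) {
  ref <- character(length(j))
  hi <- j > 26L
  ref[!hi] <- LETTERS[j[!hi]]
  ref[hi] <- paste0(LETTERS[(j[hi] - 1L) %/% 26L], LETTERS[(j[hi] - 1L) %% 26L + 1L])
  ref
}

sheet_xml <- function(df, row_styles) {
  ncol_df <- ncol(df)
  cols <- col_ref(seq_len(ncol_df))
  header <- paste0(
    '<row r="1">',
    paste0('<c r="', cols, '1" t="inlineStr" s="1"><is><t>',
           xml_escape(names(df)), "</t></is></c>", collapse = ""),
    "</row>"
  )
  body <- character(nrow(df))
  style_of <- c(0L, 2L, 3L)[pmin(row_styles, 2L) + 1L]
  for (i in seq_len(nrow(df))) {
    r <- i + 1L
    s <- style_of[i]
    cells <- vapply(seq_len(ncol_df), function(j) {
      v <- df[[j]][i]
      if (is.na(v)) return("")
      ref <- paste0(cols[j], r)
      if (is.numeric(v)) {
        sprintf('<c r="%s" s="%d"><v>%.15g</v></c>', ref, s, v)
      } else {
        sprintf('<c r="%s" s="%d" t="inlineStr"><is><t>%s</t></is></c>',
                ref, s, xml_escape(as.character(v)))
      }
    }, character(1))
    body[i] <- paste0('<row r="', r, '">', paste(cells, collapse = ""), "</row>")
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetViews><sheetView workbookViewId="0">',
    '<pane ySplit="1" topLeftCell="A2" activePane="bottomLeft" state="frozen"/>',
    "</sheetView></sheetViews>",
    "<sheetData>", header, paste(body, collapse = ""), "</sheetData>",
    "</worksheet>"
  )
}

styles_xml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="2"><font><sz val="11"/><name val="Calibri"/></font>',
    '<font><b/><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="4">',
    '<fill><patternFill patternType="none"/></fill>',
    '<fill><patternFill patternType="gray125"/></fill>',
    '<fill><patternFill patternType="solid"><fgColor rgb="FFFFC7CE"/></patternFill></fill>',
    '<fill><patternFill patternType="solid"><fgColor rgb="FFFFE699"/></patternFill></fill>',
    "</fills>",
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="4">',
    '<xf fontId="0" fillId="0" xfId="0"/>',
    '<xf fontId="1" fillId="0" xfId="0" applyFont="1"/>',
    '<xf fontId="0" fillId="2" xfId="0" applyFill="1"/>',
    '<xf fontId="0" fillId="3" xfId="0" applyFill="1"/>',
    "</cellXfs>",
    "</styleSheet>"
  )
}

# sheets: named list of data frames; row_styles: named list of integer
# vectors (0 plain, 1 red, 2 amber), one element per data row
xlsx_write <- function(sheets, path, row_styles = NULL) {
  n <- length(sheets)
  if (is.null(row_styles)) {
    row_styles <- lapply(sheets, function(df) integer(nrow(df)))
  }
  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    paste0('<Override PartName="/xl/worksheets/sheet', seq_len(n),
           '.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
           collapse = ""),
    "</Types>"
  )
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  )
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>",
    paste0('<sheet name="', xml_escape(names(sheets)), '" sheetId="', seq_len(n),
           '" r:id="rId', seq_len(n), '"/>', collapse = ""),
    "</sheets></workbook>"
  )
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste0('<Relationship Id="rId', seq_len(n),
           '" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet',
           seq_len(n), '.xml"/>', collapse = ""),
    '<Relationship Id="rId', n + 1L,
    '" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
    "</Relationships>"
  )
  parts <- c(
    list("[Content_Types].xml" = content_types,
         "_rels/.rels" = root_rels,
         "xl/workbook.xml" = workbook,
         "xl/_rels/workbook.xml.rels" = wb_rels,
         "xl/styles.xml" = styles_xml()),
    rlang::set_names(
      purrr::map2(sheets, row_styles, sheet_xml),
      paste0("xl/worksheets/sheet", seq_len(n), ".xml")
    )
  )
  zip_store(purrr::map(parts, function(x) charToRaw(enc2utf8(x))), path)
}
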