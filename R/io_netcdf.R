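# Minimal NetCDF-3 (classic, CDF-1) writer and reader.
#
# Implements exactly the subset the package's products need: fixed-size
# (non-record) variables of type byte/short/int/float/double/char on named
# dimensions, with global and per-variable attributes. Byte order is
# big-endian per the format; values are 4-byte aligned. Files written here
# are readable by any standard NetCDF library (cross-checked in the test
# suite against an independent reader).

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L
NC_INT <- 4L; NC_FLOAT <- 5L; NC_DOUBLE <- 6L
nc_type_size <- c(1L, 1L, 2L, 4L, 4L, 8L)

nc_pad <- function(n) (4L - n %% 4L) %% 4L

nc_raw_int <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")

nc_raw_name <- function(name) {
  b <- charToRaw(enc2utf8(name))
  c(nc_raw_int(length(b)), b, raw(nc_pad(length(b))))
}

nc_raw_values <- function(values, type) {
  if (type == NC_CHAR) {
    b <- charToRaw(enc2utf8(paste(values, collapse = "")))
  } else if (type == NC_DOUBLE) {
    b <- writeBin(as.double(values), raw(), size = 8L, endian = "big")
  } else if (type == NC_FLOAT) {
    b <- writeBin(as.double(values), raw(), size = 4L, endian = "big")
  } else if (type == NC_INT) {
    b <- writeBin(as.integer(values), raw(), size = 4L, endian = "big")
  } else if (type == NC_SHORT) {
    b <- writeBin(as.integer(values), raw(), size = 2L, endian = "big")
  } else if (type == NC_BYTE) {
    b <- writeBin(as.integer(values), raw(), size = 1L, endian = "big")
  } else stop("unsupported NetCDF type ", type)
  c(b, raw(nc_pad(length(b))))
}

nc_raw_attrs <- function(attrs) {
  if (!length(attrs)) return(c(nc_raw_int(0L), nc_raw_int(0L)))  # ABSENT
  out <- c(nc_raw_int(12L), nc_raw_int(length(attrs)))           # NC_ATTRIBUTE
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    type <- if (is.character(v)) NC_CHAR
    else if (is.integer(v)) NC_INT else NC_DOUBLE
    nel <- if (type == NC_CHAR) nchar(paste(v, collapse = ""), type = "bytes")
    else length(v)
    out <- c(out, nc_raw_name(nm), nc_raw_int(type), nc_raw_int(nel),
             nc_raw_values(v, type))
  }
  out
}

#' Write a NetCDF-3 classic file
#'
#' @param path output path.
#' @param dims named integer vector of dimension lengths (definition order).
#' @param vars list of variables, each
#'   `list(name, dims = <names>, type, values, attrs = <named list>)`.
#'   Values are flattened in row-major order (first listed dimension varies
#'   slowest), as the format requires.
#' @param global_attrs named list of global attributes (character, integer
#'   or double).
#' @return `path`, invisibly.
#' @keywords internal
write_netcdf_raw <- function(path, dims, vars, global_attrs = list()) {
  dim_names <- names(dims)
  header_of <- function(begins) {
    h <- c(charToRaw("CDF"), as.raw(1L), nc_raw_int(0L))     # magic + numrecs
    h <- c(h, nc_raw_int(10L), nc_raw_int(length(dims)))     # NC_DIMENSION
    for (i in seq_along(dims))
      h <- c(h, nc_raw_name(dim_names[i]), nc_raw_int(dims[[i]]))
    h <- c(h, nc_raw_attrs(global_attrs))
    h <- c(h, nc_raw_int(11L), nc_raw_int(length(vars)))     # NC_VARIABLE
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      dimids <- match(v$dims, dim_names) - 1L
      if (anyNA(dimids)) stop("undeclared dimension in variable ", v$name)
      nval <- prod(dims[v$dims])
      vsize <- nval * nc_type_size[v$type]
      vsize <- vsize + nc_pad(vsize)
      h <- c(h, nc_raw_name(v$name), nc_raw_int(length(dimids)))
      for (d in dimids) h <- c(h, nc_raw_int(d))
      h <- c(h, nc_raw_attrs(v$attrs %||% list()),
             nc_raw_int(v$type), nc_raw_int(vsize), nc_raw_int(begins[i]))
    }
    h
  }
  h0 <- header_of(rep(0L, length(vars)))
  sizes <- vapply(vars, function(v) {
    s <- prod(dims[v$dims]) * nc_type_size[v$type]
    as.integer(s + nc_pad(s))
  }, 0L)
  begins <- length(h0) + c(0L, cumsum(sizes))[seq_along(vars)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header_of(begins), con)
  for (v in vars) writeBin(nc_raw_values(v$values, v$type), con)
  invisible(path)
}

read_nc_int <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "big")

read_nc_name <- function(con) {
  n <- read_nc_int(con)
  s <- rawToChar(readBin(con, "raw", n))
  readBin(con, "raw", nc_pad(n))
  s
}

read_nc_values <- function(con, type, nel) {
  sz <- nc_type_size[type]
  out <- if (type == NC_CHAR) {
    rawToChar(readBin(con, "raw", nel))
  } else if (type == NC_DOUBLE) {
    readBin(con, "double", nel, size = 8L, endian = "big")
  } else if (type == NC_FLOAT) {
    readBin(con, "double", nel, size = 4L, endian = "big")
  } else if (type == NC_BYTE) {
    readBin(con, "integer", nel, size = 1L, endian = "big")
  } else {
    readBin(con, "integer", nel, size = sz, endian = "big")
  }
  readBin(con, "raw", nc_pad(nel * sz))
  out
}

read_nc_attrs <- function(con) {
  tag <- read_nc_int(con); n <- read_nc_int(con)
  if (tag == 0L) return(list())
  out <- list()
  for (i in seq_len(n)) {
    nm <- read_nc_name(con)
    type <- read_nc_int(con); nel <- read_nc_int(con)
    out[[nm]] <- read_nc_values(con, type, nel)
  }
  out
}

#' Read a NetCDF-3 classic file
#'
#' Reads the fixed-size-variable subset of the classic format into a list.
#'
#' @param path NetCDF-3 (CDF-1 or CDF-2) file.
#' @return List with `dims` (named lengths), `global_attrs`, and `vars`: a
#'   named list of `list(dims, type, attrs, values)`, values as an array
#'   with the declared dimensions (first declared dimension slowest).
#' @export
read_netcdf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic[1:3], charToRaw("CDF")) || !magic[4] %in% as.raw(1:2))
    stop("not a NetCDF-3 classic file: ", path)
  offset_size <- if (magic[4] == as.raw(2L)) 8L else 4L
  numrecs <- read_nc_int(con)
  tag <- read_nc_int(con); ndims <- read_nc_int(con)
  dims <- integer(0)
  if (tag == 10L) for (i in seq_len(ndims)) {
    nm <- read_nc_name(con); dims[nm] <- read_nc_int(con)
  }
  gatts <- read_nc_attrs(con)
  tag <- read_nc_int(con); nvars <- read_nc_int(con)
  vars <- list()
  if (tag == 11L) for (i in seq_len(nvars)) {
    nm <- read_nc_name(con)
    nd <- read_nc_int(con)
    dimids <- if (nd > 0) vapply(seq_len(nd), function(j) read_nc_int(con), 0L)
    else integer(0)
    atts <- read_nc_attrs(con)
    type <- read_nc_int(con)
    vsize <- read_nc_int(con)
    begin <- if (offset_size == 8L)
      readBin(con, "double", 1L, size = 8L, endian = "big")
    else read_nc_int(con)
    vars[[nm]] <- list(dims = names(dims)[dimids + 1L], type = type,
                       attrs = atts, begin = begin)
  }
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (any(dims[v$dims] == 0L)) stop("record variables not supported")
    seek(con, v$begin)
    nval <- if (length(v$dims)) prod(dims[v$dims]) else 1L
    vals <- read_nc_values(con, v$type, nval)
    if (v$type != NC_CHAR && length(v$dims) > 1L) {
      # file order is row-major (first dim slowest); R arrays are column-major
      vals <- aperm(array(vals, rev(dims[v$dims])), rev(seq_along(v$dims)))
    }
    vars[[nm]]$values <- vals
    vars[[nm]]$begin <- NULL
  }
  list(dims = dims, global_attrs = gatts, vars = vars)
}
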