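// Minimal binding to the HDF5 C library for the two containers this package
// speaks: compound record tables (one row per localization, dataset "locs")
// and flat array/string datasets used by the model bundle. Columns are
// int32 or float64; that is the full type vocabulary of the dialect.

#include <hdf5.h>
#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static void quiet_h5() {
  // HDF5 prints its own error stack to stderr by default; R errors suffice.
  H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

// [[Rcpp::export]]
void h5_write_table_(std::string path, List columns, CharacterVector col_names,
                     std::string dataset) {
  quiet_h5();
  const int ncol = columns.size();
  if (ncol == 0) stop("cannot write a table with zero columns");

  R_xlen_t nrow = Rf_xlength(columns[0]);
  std::vector<size_t> offsets(ncol);
  std::vector<bool> is_int(ncol);
  size_t rowsize = 0;
  for (int j = 0; j < ncol; ++j) {
    SEXP col = columns[j];
    if (Rf_xlength(col) != nrow) stop("column lengths differ");
    if (TYPEOF(col) == INTSXP) { is_int[j] = true; offsets[j] = rowsize; rowsize += 4; }
    else if (TYPEOF(col) == REALSXP) { is_int[j] = false; offsets[j] = rowsize; rowsize += 8; }
    else stop("column '%s' is neither integer nor double",
              std::string(col_names[j]).c_str());
  }

  hid_t ctype = H5Tcreate(H5T_COMPOUND, rowsize);
  for (int j = 0; j < ncol; ++j)
    H5Tinsert(ctype, std::string(col_names[j]).c_str(), offsets[j],
              is_int[j] ? H5T_NATIVE_INT32 : H5T_NATIVE_DOUBLE);

  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) { H5Tclose(ctype); stop("cannot create HDF5 file '%s'", path.c_str()); }

  hsize_t dims[1] = { (hsize_t) nrow };
  hid_t space = H5Screate_simple(1, dims, NULL);
  hid_t dset = H5Dcreate2(file, dataset.c_str(), ctype, space,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (dset < 0) { H5Sclose(space); H5Tclose(ctype); H5Fclose(file);
                  stop("cannot create dataset '%s'", dataset.c_str()); }

  if (nrow > 0) {
    std::vector<char> buf((size_t) nrow * rowsize);
    for (int j = 0; j < ncol; ++j) {
      if (is_int[j]) {
        const int *v = INTEGER(columns[j]);
        for (R_xlen_t i = 0; i < nrow; ++i)
          std::memcpy(&buf[(size_t) i * rowsize + offsets[j]], &v[i], 4);
      } else {
        const double *v = REAL(columns[j]);
        for (R_xlen_t i = 0; i < nrow; ++i)
          std::memcpy(&buf[(size_t) i * rowsize + offsets[j]], &v[i], 8);
      }
    }
    if (H5Dwrite(dset, ctype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data()) < 0) {
      H5Dclose(dset); H5Sclose(space); H5Tclose(ctype); H5Fclose(file);
      stop("HDF5 write failed for '%s'", path.c_str());
    }
  }
  H5Dclose(dset); H5Sclose(space); H5Tclose(ctype); H5Fclose(file);
}

// [[Rcpp::export]]
List h5_read_table_(std::string path, std::string dataset) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  hid_t dset = H5Dopen2(file, dataset.c_str(), H5P_DEFAULT);
  if (dset < 0) { H5Fclose(file); stop("dataset '%s' not found in '%s'",
                                       dataset.c_str(), path.c_str()); }
  hid_t ftype = H5Dget_type(dset);
  if (H5Tget_class(ftype) != H5T_COMPOUND) {
    H5Tclose(ftype); H5Dclose(dset); H5Fclose(file);
    stop("dataset '%s' is not a record table", dataset.c_str());
  }
  hid_t space = H5Dget_space(dset);
  hssize_t n = H5Sget_simple_extent_npoints(space);
  int nm = H5Tget_nmembers(ftype);

  List out(nm);
  CharacterVector names(nm);
  for (int j = 0; j < nm; ++j) {
    char *mname = H5Tget_member_name(ftype, (unsigned) j);
    names[j] = mname;
    hid_t mtype = H5Tget_member_type(ftype, (unsigned) j);
    H5T_class_t cls = H5Tget_class(mtype);
    if (cls == H5T_INTEGER) {
      IntegerVector v((R_xlen_t) n);
      hid_t mem = H5Tcreate(H5T_COMPOUND, 4);
      H5Tinsert(mem, mname, 0, H5T_NATIVE_INT32);
      if (n > 0 && H5Dread(dset, mem, H5S_ALL, H5S_ALL, H5P_DEFAULT, INTEGER(v)) < 0) {
        H5Tclose(mem); H5Tclose(mtype); stop("HDF5 read failed for column '%s'", mname);
      }
      H5Tclose(mem);
      out[j] = v;
    } else if (cls == H5T_FLOAT) {
      NumericVector v((R_xlen_t) n);
      hid_t mem = H5Tcreate(H5T_COMPOUND, 8);
      H5Tinsert(mem, mname, 0, H5T_NATIVE_DOUBLE);
      if (n > 0 && H5Dread(dset, mem, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(v)) < 0) {
        H5Tclose(mem); H5Tclose(mtype); stop("HDF5 read failed for column '%s'", mname);
      }
      H5Tclose(mem);
      out[j] = v;
    } else {
      H5Tclose(mtype); H5Tclose(ftype); H5Sclose(space); H5Dclose(dset); H5Fclose(file);
      stop("column '%s' has an unsupported HDF5 type class", mname);
    }
    H5Tclose(mtype);
    H5free_memory(mname);
  }
  out.attr("names") = names;
  H5Tclose(ftype); H5Sclose(space); H5Dclose(dset); H5Fclose(file);
  return out;
}

// [[Rcpp::export]]
void h5_create_file_(std::string path) {
  quiet_h5();
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) stop("cannot create HDF5 file '%s'", path.c_str());
  H5Fclose(file);
}

// data is row-major relative to dims.
// [[Rcpp::export]]
void h5_write_array_(std::string path, std::string name, NumericVector data,
                     IntegerVector dims) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDWR, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s' for writing", path.c_str());
  std::vector<hsize_t> hdims(dims.begin(), dims.end());
  hid_t space = H5Screate_simple((int) hdims.size(), hdims.data(), NULL);
  hid_t dset = H5Dcreate2(file, name.c_str(), H5T_NATIVE_DOUBLE, space,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (dset < 0) { H5Sclose(space); H5Fclose(file);
                  stop("cannot create dataset '%s'", name.c_str()); }
  if (data.size() > 0 &&
      H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(data)) < 0) {
    H5Dclose(dset); H5Sclose(space); H5Fclose(file);
    stop("HDF5 write failed for '%s'", name.c_str());
  }
  H5Dclose(dset); H5Sclose(space); H5Fclose(file);
}

// [[Rcpp::export]]
List h5_read_array_(std::string path, std::string name) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  hid_t dset = H5Dopen2(file, name.c_str(), H5P_DEFAULT);
  if (dset < 0) { H5Fclose(file); stop("dataset '%s' not found", name.c_str()); }
  hid_t space = H5Dget_space(dset);
  int rank = H5Sget_simple_extent_ndims(space);
  std::vector<hsize_t> hdims(rank > 0 ? rank : 1);
  H5Sget_simple_extent_dims(space, hdims.data(), NULL);
  hssize_t n = H5Sget_simple_extent_npoints(space);
  NumericVector data((R_xlen_t) n);
  if (n > 0 &&
      H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(data)) < 0) {
    H5Sclose(space); H5Dclose(dset); H5Fclose(file);
    stop("HDF5 read failed for '%s'", name.c_str());
  }
  IntegerVector dims(rank);
  for (int i = 0; i < rank; ++i) dims[i] = (int) hdims[i];
  H5Sclose(space); H5Dclose(dset); H5Fclose(file);
  return List::create(Named("data") = data, Named("dims") = dims);
}

// [[Rcpp::export]]
void h5_write_string_(std::string path, std::string name, std::string value) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDWR, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s' for writing", path.c_str());
  hid_t stype = H5Tcopy(H5T_C_S1);
  H5Tset_size(stype, value.size() + 1);
  H5Tset_strpad(stype, H5T_STR_NULLTERM);
  hid_t space = H5Screate(H5S_SCALAR);
  hid_t dset = H5Dcreate2(file, name.c_str(), stype, space,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
  if (dset < 0) { H5Sclose(space); H5Tclose(stype); H5Fclose(file);
                  stop("cannot create dataset '%s'", name.c_str()); }
  if (H5Dwrite(dset, stype, H5S_ALL, H5S_ALL, H5P_DEFAULT, value.c_str()) < 0) {
    H5Dclose(dset); H5Sclose(space); H5Tclose(stype); H5Fclose(file);
    stop("HDF5 write failed for '%s'", name.c_str());
  }
  H5Dclose(dset); H5Sclose(space); H5Tclose(stype); H5Fclose(file);
}

// [[Rcpp::export]]
std::string h5_read_string_(std::string path, std::string name) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  hid_t dset = H5Dopen2(file, name.c_str(), H5P_DEFAULT);
  if (dset < 0) { H5Fclose(file); stop("dataset '%s' not found", name.c_str()); }
  hid_t ftype = H5Dget_type(dset);
  size_t sz = H5Tget_size(ftype);
  std::vector<char> buf(sz + 1, '\0');
  hid_t mtype = H5Tcopy(H5T_C_S1);
  H5Tset_size(mtype, sz + 1);
  if (H5Dread(dset, mtype, H5S_ALL, H5S_ALL, H5P_DEFAULT, buf.data()) < 0) {
    H5Tclose(mtype); H5Tclose(ftype); H5Dclose(dset); H5Fclose(file);
    stop("HDF5 read failed for '%s'", name.c_str());
  }
  std::string out(buf.data());
  H5Tclose(mtype); H5Tclose(ftype); H5Dclose(dset); H5Fclose(file);
  return out;
}

// [[Rcpp::export]]
CharacterVector h5_ls_(std::string path) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  H5G_info_t info;
  H5Gget_info(file, &info);
  CharacterVector out((R_xlen_t) info.nlinks);
  for (hsize_t i = 0; i < info.nlinks; ++i) {
    ssize_t len = H5Lget_name_by_idx(file, ".", H5_INDEX_NAME, H5_ITER_INC, i,
                                     NULL, 0, H5P_DEFAULT);
    std::vector<char> buf((size_t) len + 1, '\0');
    H5Lget_name_by_idx(file, ".", H5_INDEX_NAME, H5_ITER_INC, i,
                       buf.data(), (size_t) len + 1, H5P_DEFAULT);
    out[(R_xlen_t) i] = std::string(buf.data());
  }
  H5Fclose(file);
  return out;
}

// [[Rcpp::export]]
bool h5_has_dataset_(std::string path, std::string name) {
  quiet_h5();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  htri_t ex = H5Lexists(file, name.c_str(), H5P_DEFAULT);
  H5Fclose(file);
  return ex > 0;
}
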