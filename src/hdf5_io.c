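/* Minimal HDF5 reader/writer for the documented recording layout:
 *   /recording/traces               float32, dims (n_channels, n_samples)
 *   /recording/sample_rate_hz       float64 scalar
 *   /recording/pitch_um             float64 scalar
 *   /recording/start_time_s         float64 scalar
 *   /recording/channels/row         int32, length n_channels
 *   /recording/channels/col        int32
 *   /recording/channels/linear_index int32
 *
 * The traces dataset is channel-major, so one channel's samples are
 * contiguous on disk and a channel subset can be read without touching
 * other channels' data.
 */
#include <hdf5.h>
#include <stdlib.h>
#include <string.h>

#include <R.h>
#include <Rinternals.h>

static void h5_fail(hid_t file, const char *msg, const char *path)
{
    if (file >= 0) H5Fclose(file);
    Rf_error("%s: '%s'", msg, path);
}

static void write_scalar_double(hid_t loc, const char *name, double value)
{
    hid_t space = H5Screate(H5S_SCALAR);
    hid_t dset = H5Dcreate2(loc, name, H5T_IEEE_F64LE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &value);
    H5Dclose(dset);
    H5Sclose(space);
}

static void write_int_vector(hid_t loc, const char *name, const int *data, hsize_t n)
{
    hid_t space = H5Screate_simple(1, &n, NULL);
    hid_t dset = H5Dcreate2(loc, name, H5T_STD_I32LE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT, data);
    H5Dclose(dset);
    H5Sclose(space);
}

/* traces: R matrix n_samples x n_channels (column-major), so each channel is
 * contiguous in memory, matching the row-major (n_channels, n_samples) layout. */
SEXP C_h5_write(SEXP path, SEXP traces, SEXP row, SEXP col, SEXP lin,
                SEXP rate, SEXP pitch, SEXP start_time)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    SEXP dim = Rf_getAttrib(traces, R_DimSymbol);
    hsize_t nsamp = (hsize_t) INTEGER(dim)[0];
    hsize_t nchan = (hsize_t) INTEGER(dim)[1];

    hid_t file = H5Fcreate(fname, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) h5_fail(-1, "cannot create HDF5 file", fname);

    hid_t grp = H5Gcreate2(file, "/recording", H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);

    hsize_t dims[2] = { nchan, nsamp };
    hid_t space = H5Screate_simple(2, dims, NULL);
    hid_t dset = H5Dcreate2(grp, "traces", H5T_IEEE_F32LE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (dset < 0) { H5Gclose(grp); h5_fail(file, "cannot create traces dataset", fname); }
    herr_t st = H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                         REAL(traces));
    H5Dclose(dset);
    H5Sclose(space);
    if (st < 0) { H5Gclose(grp); h5_fail(file, "failed writing traces", fname); }

    write_scalar_double(grp, "sample_rate_hz", Rf_asReal(rate));
    write_scalar_double(grp, "pitch_um", Rf_asReal(pitch));
    write_scalar_double(grp, "start_time_s", Rf_asReal(start_time));

    hid_t cgrp = H5Gcreate2(grp, "channels", H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    write_int_vector(cgrp, "row", INTEGER(row), nchan);
    write_int_vector(cgrp, "col", INTEGER(col), nchan);
    write_int_vector(cgrp, "linear_index", INTEGER(lin), nchan);
    H5Gclose(cgrp);

    H5Gclose(grp);
    H5Fclose(file);
    return path;
}

static double read_scalar_double(hid_t file, const char *name, const char *fname)
{
    hid_t dset = H5Dopen2(file, name, H5P_DEFAULT);
    if (dset < 0) h5_fail(file, "malformed recording file (missing dataset)", fname);
    double value = 0;
    herr_t st = H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &value);
    H5Dclose(dset);
    if (st < 0) h5_fail(file, "failed reading scalar", fname);
    return value;
}

static SEXP read_int_vector(hid_t file, const char *name, hsize_t expect_n,
                            const char *fname)
{
    hid_t dset = H5Dopen2(file, name, H5P_DEFAULT);
    if (dset < 0) h5_fail(file, "malformed recording file (missing channel table)", fname);
    hid_t space = H5Dget_space(dset);
    hsize_t n;
    H5Sget_simple_extent_dims(space, &n, NULL);
    H5Sclose(space);
    if (n != expect_n) { H5Dclose(dset); h5_fail(file, "channel table length mismatch", fname); }
    SEXP out = PROTECT(Rf_allocVector(INTSXP, (R_xlen_t) n));
    herr_t st = H5Dread(dset, H5T_NATIVE_INT, H5S_ALL, H5S_ALL, H5P_DEFAULT, INTEGER(out));
    H5Dclose(dset);
    if (st < 0) h5_fail(file, "failed reading channel table", fname);
    UNPROTECT(1);
    return out;
}

/* Metadata only: channel table, rates, trace extent. */
SEXP C_h5_read_meta(SEXP path)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) h5_fail(-1, "cannot open HDF5 file", fname);

    hid_t dset = H5Dopen2(file, "/recording/traces", H5P_DEFAULT);
    if (dset < 0) h5_fail(file, "malformed recording file (missing /recording/traces)", fname);
    hid_t space = H5Dget_space(dset);
    hsize_t dims[2];
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 2) { H5Sclose(space); H5Dclose(dset); h5_fail(file, "traces dataset is not 2-D", fname); }
    H5Sget_simple_extent_dims(space, dims, NULL);
    H5Sclose(space);
    H5Dclose(dset);

    SEXP out = PROTECT(Rf_allocVector(VECSXP, 7));
    SEXP names = PROTECT(Rf_allocVector(STRSXP, 7));
    const char *nm[7] = { "row", "col", "linear_index", "sample_rate_hz",
                          "pitch_um", "start_time_s", "n_samples" };
    for (int i = 0; i < 7; i++) SET_STRING_ELT(names, i, Rf_mkChar(nm[i]));
    Rf_setAttrib(out, R_NamesSymbol, names);

    SET_VECTOR_ELT(out, 0, read_int_vector(file, "/recording/channels/row", dims[0], fname));
    SET_VECTOR_ELT(out, 1, read_int_vector(file, "/recording/channels/col", dims[0], fname));
    SET_VECTOR_ELT(out, 2, read_int_vector(file, "/recording/channels/linear_index", dims[0], fname));
    SET_VECTOR_ELT(out, 3, Rf_ScalarReal(read_scalar_double(file, "/recording/sample_rate_hz", fname)));
    SET_VECTOR_ELT(out, 4, Rf_ScalarReal(read_scalar_double(file, "/recording/pitch_um", fname)));
    SET_VECTOR_ELT(out, 5, Rf_ScalarReal(read_scalar_double(file, "/recording/start_time_s", fname)));
    SET_VECTOR_ELT(out, 6, Rf_ScalarReal((double) dims[1]));

    H5Fclose(file);
    UNPROTECT(2);
    return out;
}

/* Selective trace read: chan_idx0 = 0-based file channel indices,
 * samples [samp_start, samp_start + samp_count). One hyperslab per channel;
 * unrequested channels are never read. */
SEXP C_h5_read_traces(SEXP path, SEXP chan_idx0, SEXP samp_start, SEXP samp_count)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    R_xlen_t nsel = Rf_xlength(chan_idx0);
    hsize_t s0 = (hsize_t) Rf_asReal(samp_start);
    hsize_t ns = (hsize_t) Rf_asReal(samp_count);

    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) h5_fail(-1, "cannot open HDF5 file", fname);
    hid_t dset = H5Dopen2(file, "/recording/traces", H5P_DEFAULT);
    if (dset < 0) h5_fail(file, "malformed recording file (missing /recording/traces)", fname);
    hid_t fspace = H5Dget_space(dset);
    hsize_t dims[2];
    H5Sget_simple_extent_dims(fspace, dims, NULL);

    SEXP out = PROTECT(Rf_allocMatrix(REALSXP, (int) ns, (int) nsel));
    hsize_t mdims = ns;
    hid_t mspace = H5Screate_simple(1, &mdims, NULL);

    for (R_xlen_t j = 0; j < nsel; j++) {
        hsize_t start[2] = { (hsize_t) INTEGER(chan_idx0)[j], s0 };
        hsize_t count[2] = { 1, ns };
        if (start[0] >= dims[0] || s0 + ns > dims[1]) {
            H5Sclose(mspace); H5Sclose(fspace); H5Dclose(dset);
            h5_fail(file, "requested slab outside traces extent", fname);
        }
        H5Sselect_hyperslab(fspace, H5S_SELECT_SET, start, NULL, count, NULL);
        herr_t st = H5Dread(dset, H5T_NATIVE_DOUBLE, mspace, fspace, H5P_DEFAULT,
                            REAL(out) + (R_xlen_t) ns * j);
        if (st < 0) {
            H5Sclose(mspace); H5Sclose(fspace); H5Dclose(dset);
            h5_fail(file, "failed reading traces slab", fname);
        }
    }

    H5Sclose(mspace);
    H5Sclose(fspace);
    H5Dclose(dset);
    H5Fclose(file);
    UNPROTECT(1);
    return out;
}
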