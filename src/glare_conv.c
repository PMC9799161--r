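/* FFT convolution of a scene with a full-image glare kernel.
 *
 * The scene (N1 x N2) is embedded, with replicate or constant padding of
 * width R (the kernel radius), into an L1 x L2 transform grid (L >= N + 2R,
 * composite sizes chosen by the caller).  The kernel (side 2R+1) is
 * embedded origin-centered (wrapped to the grid corners); being even in
 * both axes its spectrum is real, so it is stored at half size.  Circular
 * wrap-around then only touches the padding margin and the cropped interior
 * is the exact linear convolution of the padded scene.
 *
 * Everything runs in three buffers (one real grid, one half-spectrum
 * complex grid, one half-spectrum real grid), allocated through R_alloc so
 * peak memory stays close to the theoretical minimum for images whose
 * kernels reach several gigapixels.
 */

#include <R.h>
#include <Rinternals.h>
#include <fftw3.h>

SEXP C_glare_convolve(SEXP x_, SEXP ker_, SEXP radius_, SEXP constant_,
                      SEXP L1_, SEXP L2_)
{
    const double *x = REAL(x_);
    const double *ker = REAL(ker_);
    const int N1 = Rf_nrows(x_), N2 = Rf_ncols(x_);
    const int R_px = Rf_asInteger(radius_);
    const double cval = Rf_asReal(constant_);   /* NA => replicate */
    const int replicate = ISNA(cval);
    const R_xlen_t L1 = Rf_asInteger(L1_), L2 = Rf_asInteger(L2_);
    const int side = Rf_nrows(ker_);
    const R_xlen_t n1c = L1 / 2 + 1;
    const int P1 = N1 + 2 * R_px, P2 = N2 + 2 * R_px;

    if (side != 2 * R_px + 1 || side != Rf_ncols(ker_))
        Rf_error("kernel side does not match the radius");
    if (L1 < P1 || L2 < P2)
        Rf_error("transform grid smaller than the padded image");

    double *A = (double *) R_alloc((size_t) L1 * L2, sizeof(double));
    fftw_complex *C =
        (fftw_complex *) R_alloc((size_t) n1c * L2, sizeof(fftw_complex));
    double *Kr = (double *) R_alloc((size_t) n1c * L2, sizeof(double));

    /* FFTW is row-major: treat the column-major L1 x L2 grid as a
     * row-major L2 x L1 array, so the halved dimension is L1. */
    fftw_plan fwd = fftw_plan_dft_r2c_2d((int) L2, (int) L1, A, C,
                                         FFTW_ESTIMATE);
    fftw_plan bwd = fftw_plan_dft_c2r_2d((int) L2, (int) L1, C, A,
                                         FFTW_ESTIMATE);
    if (!fwd || !bwd) Rf_error("FFTW plan creation failed");

    /* ---- kernel spectrum (real, by even symmetry) -------------------- */
    memset(A, 0, (size_t) L1 * L2 * sizeof(double));
    for (int j = 0; j < side; j++) {
        R_xlen_t jw = (j - R_px + L2) % L2;
        const double *kcol = ker + (R_xlen_t) j * side;
        double *acol = A + jw * L1;
        for (int i = 0; i < side; i++)
            acol[(i - R_px + L1) % L1] = kcol[i];
    }
    fftw_execute(fwd);
    for (R_xlen_t t = 0; t < n1c * L2; t++)
        Kr[t] = C[t][0];

    /* ---- padded scene spectrum ---------------------------------------- */
    memset(A, 0, (size_t) L1 * L2 * sizeof(double));
    for (int jj = 0; jj < P2; jj++) {
        int sj = jj - R_px;
        double *acol = A + (R_xlen_t) jj * L1;
        if (replicate) {
            sj = sj < 0 ? 0 : (sj >= N2 ? N2 - 1 : sj);
            const double *xcol = x + (R_xlen_t) sj * N1;
            for (int ii = 0; ii < P1; ii++) {
                int si = ii - R_px;
                si = si < 0 ? 0 : (si >= N1 ? N1 - 1 : si);
                acol[ii] = xcol[si];
            }
        } else if (sj < 0 || sj >= N2) {
            for (int ii = 0; ii < P1; ii++) acol[ii] = cval;
        } else {
            const double *xcol = x + (R_xlen_t) sj * N1;
            for (int ii = 0; ii < P1; ii++) {
                int si = ii - R_px;
                acol[ii] = (si < 0 || si >= N1) ? cval : xcol[si];
            }
        }
    }
    fftw_execute(fwd);

    /* ---- multiply and invert ------------------------------------------ */
    for (R_xlen_t t = 0; t < n1c * L2; t++) {
        C[t][0] *= Kr[t];
        C[t][1] *= Kr[t];
    }
    fftw_execute(bwd);
    fftw_destroy_plan(fwd);
    fftw_destroy_plan(bwd);

    /* ---- scale and crop the interior ---------------------------------- */
    SEXP out = PROTECT(Rf_allocMatrix(REALSXP, N1, N2));
    double *o = REAL(out);
    const double scale = 1.0 / ((double) L1 * (double) L2);
    for (int j = 0; j < N2; j++) {
        const double *acol = A + (R_xlen_t) (j + R_px) * L1 + R_px;
        double *ocol = o + (R_xlen_t) j * N1;
        for (int i = 0; i < N1; i++)
            ocol[i] = acol[i] * scale;
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_glare_convolve", (DL_FUNC) &C_glare_convolve, 6},
    {NULL, NULL, 0}
};

void R_init_retinaglare(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
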