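/* Grayscale morphological erosion/dilation with a flat disc structuring
 * element, used for rolling-ball background estimation (opening = erosion
 * then dilation).  The disc is decomposed into horizontal chords: a 1-D
 * min/max filter along x per distinct chord half-width, then a combine
 * over the vertical offsets.  Pixels outside the image are ignored.
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <float.h>

static void minmax_filter_x(const double *in, double *out, int nx, int ny,
                            int w, int do_max)
{
    for (int y = 0; y < ny; y++) {
        const double *col = in + (size_t) y * nx;
        double *o = out + (size_t) y * nx;
        for (int x = 0; x < nx; x++) {
            int lo = x - w < 0 ? 0 : x - w;
            int hi = x + w >= nx ? nx - 1 : x + w;
            double v = col[lo];
            for (int k = lo + 1; k <= hi; k++) {
                if (do_max ? col[k] > v : col[k] < v) v = col[k];
            }
            o[x] = v;
        }
    }
}

void arpkin_gray_morph(double *img, int *nx_, int *ny_, int *radius_,
                       int *do_max_, double *out)
{
    int nx = *nx_, ny = *ny_, r = *radius_, do_max = *do_max_;
    size_t n = (size_t) nx * ny;
    double init = do_max ? -DBL_MAX : DBL_MAX;
    double *tmp = (double *) R_alloc(n * (r + 1), sizeof(double));
    int computed[64];

    for (int w = 0; w <= r && w < 64; w++) computed[w] = 0;
    for (size_t i = 0; i < n; i++) out[i] = init;

    for (int dy = -r; dy <= r; dy++) {
        int w = (int) sqrt((double) r * r - (double) dy * dy);
        double *t = tmp + (size_t) w * n;
        if (!computed[w]) {
            minmax_filter_x(img, t, nx, ny, w, do_max);
            computed[w] = 1;
        }
        int y0 = dy < 0 ? -dy : 0;
        int y1 = dy > 0 ? ny - dy : ny;
        for (int y = y0; y < y1; y++) {
            const double *t_col = t + (size_t)(y + dy) * nx;
            double *o = out + (size_t) y * nx;
            for (int x = 0; x < nx; x++) {
                if (do_max ? t_col[x] > o[x] : t_col[x] < o[x])
                    o[x] = t_col[x];
            }
        }
    }
}
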