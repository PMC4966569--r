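#include <Rcpp.h>
using namespace Rcpp;

// Bootstrap gather-and-sum: W is a (nstat x nwin x nreg) count array.
// Each repetition draws one window uniformly per region and sums the
// per-window count vectors over regions. Uses R's RNG so draws are
// reproducible under set.seed().
//
// [[Rcpp::export]]
NumericMatrix boot_window_sums(NumericVector W, int reps) {
    IntegerVector dim = W.attr("dim");
    if (dim.size() != 3)
        stop("W must be a 3-d array (nstat x nwin x nreg)");
    const int nstat = dim[0], nwin = dim[1], nreg = dim[2];
    NumericMatrix out(reps, nstat);
    const double *w = W.begin();
    std::vector<double> acc(nstat);
    for (int r = 0; r < reps; ++r) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int j = 0; j < nreg; ++j) {
            int win = (int)(unif_rand() * nwin);
            if (win >= nwin) win = nwin - 1; // guard unif_rand()==1
            const double *base = w + ((size_t)j * nwin + win) * nstat;
            for (int k = 0; k < nstat; ++k) acc[k] += base[k];
        }
        for (int k = 0; k < nstat; ++k) out(r, k) = acc[k];
    }
    return out;
}
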