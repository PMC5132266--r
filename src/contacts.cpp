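#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Cell-list contact detection between residue beads and lipid beads
// over all frames of a trajectory, emitting maximal runs of consecutive
// contact frames per (residue group, lipid group) pair.
//
// coords: array with dim (F, B, 3), Angstrom
// resBead / lipBead: 1-based bead indices; resOf / lipOf: 1-based group
// index of each bead (residue number / lipid molecule number)
// box: F x 3 box lengths; pbc: use minimum image
//
// Returns a DataFrame(res, lip, start, end), all 1-based.
// [[Rcpp::export]]
DataFrame contact_runs_cpp(NumericVector coords,
                           IntegerVector resBead, IntegerVector resOf,
                           IntegerVector lipBead, IntegerVector lipOf,
                           NumericMatrix box, double cutoff, bool pbc) {
    IntegerVector dims = coords.attr("dim");
    const int F = dims[0], B = dims[1];
    const int nrb = resBead.size(), nlb = lipBead.size();
    int nRes = 0, nLip = 0;
    for (int i = 0; i < nrb; ++i) nRes = std::max(nRes, resOf[i]);
    for (int i = 0; i < nlb; ++i) nLip = std::max(nLip, lipOf[i]);
    const double cut2 = cutoff * cutoff;
    const double *C = REAL(coords);

    std::vector<int> runStart((size_t)nRes * nLip, -1);
    std::vector<unsigned char> hit((size_t)nRes * nLip);
    std::vector<int> outRes, outLip, outStart, outEnd;

    std::vector<double> lx(nlb), ly(nlb), lz(nlb);
    std::vector<int> cellHead, cellNext(nlb);

    for (int f = 0; f < F; ++f) {
        std::memset(hit.data(), 0, hit.size());
        const double bx = box(f, 0), by = box(f, 1), bz = box(f, 2);
        // cell grid: edge >= cutoff
        int ncx = std::max(1, (int)std::floor(bx / cutoff));
        int ncy = std::max(1, (int)std::floor(by / cutoff));
        int ncz = std::max(1, (int)std::floor(bz / cutoff));
        const int ncells = ncx * ncy * ncz;
        cellHead.assign(ncells, -1);

        for (int j = 0; j < nlb; ++j) {
            const int b = lipBead[j] - 1;
            double x = C[f + (size_t)F * b];
            double y = C[f + (size_t)F * (b + (size_t)B)];
            double z = C[f + (size_t)F * (b + 2 * (size_t)B)];
            if (pbc) {  // wrap into the primary cell for hashing
                x -= bx * std::floor(x / bx);
                y -= by * std::floor(y / by);
                z -= bz * std::floor(z / bz);
            }
            lx[j] = x; ly[j] = y; lz[j] = z;
            int cx = std::min(ncx - 1, std::max(0, (int)(x / bx * ncx)));
            int cy = std::min(ncy - 1, std::max(0, (int)(y / by * ncy)));
            int cz = std::min(ncz - 1, std::max(0, (int)(z / bz * ncz)));
            const int c = (cz * ncy + cy) * ncx + cx;
            cellNext[j] = cellHead[c];
            cellHead[c] = j;
        }

        for (int i = 0; i < nrb; ++i) {
            const int b = resBead[i] - 1;
            const int gi = resOf[i] - 1;
            double x = C[f + (size_t)F * b];
            double y = C[f + (size_t)F * (b + (size_t)B)];
            double z = C[f + (size_t)F * (b + 2 * (size_t)B)];
            double wx = x, wy = y, wz = z;
            if (pbc) {
                wx -= bx * std::floor(x / bx);
                wy -= by * std::floor(y / by);
                wz -= bz * std::floor(z / bz);
            }
            int cx = std::min(ncx - 1, std::max(0, (int)(wx / bx * ncx)));
            int cy = std::min(ncy - 1, std::max(0, (int)(wy / by * ncy)));
            int cz = std::min(ncz - 1, std::max(0, (int)(wz / bz * ncz)));
            for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int ex = cx + dx, ey = cy + dy, ez = cz + dz;
                if (pbc) {
                    ex = (ex + ncx) % ncx;
                    ey = (ey + ncy) % ncy;
                    ez = (ez + ncz) % ncz;
                } else if (ex < 0 || ey < 0 || ez < 0 ||
                           ex >= ncx || ey >= ncy || ez >= ncz) {
                    continue;
                }
                const int c = (ez * ncy + ey) * ncx + ex;
                for (int j = cellHead[c]; j >= 0; j = cellNext[j]) {
                    const int gj = lipOf[j] - 1;
                    if (hit[(size_t)gi * nLip + gj])
                        continue;
                    double ddx = wx - lx[j], ddy = wy - ly[j], ddz = wz - lz[j];
                    if (pbc) {
                        ddx -= bx * std::round(ddx / bx);
                        ddy -= by * std::round(ddy / by);
                        ddz -= bz * std::round(ddz / bz);
                    }
                    const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                    if (d2 <= cut2)
                        hit[(size_t)gi * nLip + gj] = 1;
                }
            }
        }

        for (size_t p = 0; p < hit.size(); ++p) {
            if (hit[p]) {
                if (runStart[p] < 0) runStart[p] = f;
            } else if (runStart[p] >= 0) {
                outRes.push_back((int)(p / nLip) + 1);
                outLip.push_back((int)(p % nLip) + 1);
                outStart.push_back(runStart[p] + 1);
                outEnd.push_back(f);
                runStart[p] = -1;
            }
        }
    }
    for (size_t p = 0; p < runStart.size(); ++p) {
        if (runStart[p] >= 0) {
            outRes.push_back((int)(p / nLip) + 1);
            outLip.push_back((int)(p % nLip) + 1);
            outStart.push_back(runStart[p] + 1);
            outEnd.push_back(F);
        }
    }
    return DataFrame::create(_["res"] = outRes, _["lip"] = outLip,
                             _["start"] = outStart, _["end"] = outEnd);
}
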