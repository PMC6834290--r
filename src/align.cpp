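#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Complement of an uppercase base; anything unexpected maps to 'N'.
static inline char comp(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Exhaustive scan of every protospacer against every offset on both strands
// of every chromosome, keeping hits with <= max_mismatch mismatches over the
// 20-nt protospacer and a canonical NGG PAM immediately 3' of the protospacer
// on the hit strand. Coordinates are 0-based half-open on the forward strand.
// Mismatch positions are 1..20 counted from the PAM-distal (5') end of the
// protospacer. Hits whose PAM would fall beyond the contig end are discarded
// and counted; hits with a non-NGG PAM are discarded and counted.
// [[Rcpp::export]]
List scan_guides_cpp(CharacterVector chrom_seqs, CharacterVector protospacers,
                     int max_mismatch) {
  const int n_chrom = chrom_seqs.size();
  const int n_guide = protospacers.size();
  const int W = 20;

  std::vector<int> out_guide, out_chrom, out_start, out_nmm, out_mm1, out_mm2;
  std::vector<int> out_strand; // 1 = '+', -1 = '-'
  std::vector<std::string> out_pam;
  long long n_no_pam_room = 0, n_noncanonical = 0;

  std::vector<std::string> fw(n_guide), rc(n_guide);
  for (int g = 0; g < n_guide; ++g) {
    std::string p = as<std::string>(protospacers[g]);
    if ((int)p.size() != W) stop("protospacer must be exactly 20 nt");
    fw[g] = p;
    std::string r(W, 'N');
    for (int j = 0; j < W; ++j) r[j] = comp(p[W - 1 - j]);
    rc[g] = r;
  }

  for (int c = 0; c < n_chrom; ++c) {
    std::string seq = as<std::string>(chrom_seqs[c]);
    const int L = (int)seq.size();
    const char *s = seq.c_str();
    for (int g = 0; g < n_guide; ++g) {
      const char *pf = fw[g].c_str();
      const char *pr = rc[g].c_str();
      for (int pos = 0; pos + W <= L; ++pos) {
        // forward strand: protospacer at [pos, pos+20), PAM at [pos+20, pos+23)
        {
          int nmm = 0, mm1 = NA_INTEGER, mm2 = NA_INTEGER;
          for (int j = 0; j < W; ++j) {
            if (s[pos + j] != pf[j]) {
              ++nmm;
              if (nmm > max_mismatch) break;
              if (nmm == 1) mm1 = j + 1; else if (nmm == 2) mm2 = j + 1;
            }
          }
          if (nmm <= max_mismatch) {
            if (pos + W + 3 > L) {
              ++n_no_pam_room;
            } else if (s[pos + W + 1] == 'G' && s[pos + W + 2] == 'G') {
              out_guide.push_back(g + 1); out_chrom.push_back(c + 1);
              out_strand.push_back(1); out_start.push_back(pos);
              out_nmm.push_back(nmm); out_mm1.push_back(mm1); out_mm2.push_back(mm2);
              out_pam.push_back(seq.substr(pos + W, 3));
            } else {
              ++n_noncanonical;
            }
          }
        }
        // reverse strand: revcomp(protospacer) at forward [pos, pos+20),
        // PAM (on hit strand) is revcomp of forward [pos-3, pos).
        {
          int nmm = 0, mm1 = NA_INTEGER, mm2 = NA_INTEGER;
          for (int j = 0; j < W; ++j) {
            if (s[pos + j] != pr[j]) {
              ++nmm;
              if (nmm > max_mismatch) break;
              // rc index j corresponds to protospacer position 20 - j
              int p_pos = W - j;
              if (nmm == 1) mm1 = p_pos; else if (nmm == 2) mm2 = p_pos;
            }
          }
          if (nmm <= max_mismatch) {
            if (pos - 3 < 0) {
              ++n_no_pam_room;
            } else if (s[pos - 2] == 'C' && s[pos - 3] == 'C') {
              // hit-strand PAM = comp(seq[pos-1]), comp(seq[pos-2]), comp(seq[pos-3])
              std::string pam(3, 'N');
              pam[0] = comp(s[pos - 1]); pam[1] = comp(s[pos - 2]); pam[2] = comp(s[pos - 3]);
              // order mismatch positions ascending in protospacer coordinates
              if (nmm == 2 && mm1 > mm2) std::swap(mm1, mm2);
              out_guide.push_back(g + 1); out_chrom.push_back(c + 1);
              out_strand.push_back(-1); out_start.push_back(pos);
              out_nmm.push_back(nmm); out_mm1.push_back(mm1); out_mm2.push_back(mm2);
              out_pam.push_back(pam);
            } else {
              ++n_noncanonical;
            }
          }
        }
      }
    }
  }

  return List::create(
    _["guide"] = wrap(out_guide), _["chrom"] = wrap(out_chrom),
    _["strand"] = wrap(out_strand), _["start"] = wrap(out_start),
    _["n_mismatches"] = wrap(out_nmm), _["mm1"] = wrap(out_mm1),
    _["mm2"] = wrap(out_mm2), _["pam"] = wrap(out_pam),
    _["n_end_clipped"] = (double)n_no_pam_room,
    _["n_noncanonical"] = (double)n_noncanonical);
}
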