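#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// Training churns through large short-lived activation tensors. With the
// default glibc settings every such allocation is a fresh mmap whose pages
// must be faulted in on first touch, which dominates runtime on slow-page
// virtualized hosts. Keeping large allocations on the heap (no mmap, no
// trim) lets freed pages be reused warm.
// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_MAX, 0);
  mallopt(M_TRIM_THRESHOLD, -1);
#endif
}
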