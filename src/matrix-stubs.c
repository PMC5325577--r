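/* Instantiates the CHOLMOD entry points exported by the Matrix package
   (LinkingTo: Matrix); see Matrix's API documentation. */
#include <Matrix/cholmod.h>
#include <Matrix/stubs.c>
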