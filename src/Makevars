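# Build with the system toolchain: the bundled cross-compiler targets a
# newer glibc than the runtime loader provides, so its objects fail to
# load ("version GLIBC_2.38 not found").
override CXX = g++
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override CXX20 = g++
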