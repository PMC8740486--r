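a
an
and
are
as
at
be
been
being
but
by
for
from
had
has
have
in
into
is
it
its
of
on
or
our
such
than
that
the
their
then
there
these
they
this
those
to
was
we
were
which
while
who
whose
will
with
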