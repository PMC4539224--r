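#' Credential envelopes and impersonated execution
#'
#' To run commands under a user's own identity, credentials are encrypted
#' with the executor's RSA public key at the boundary where they arrive;
#' from that moment on they exist only as ciphertext anywhere the system
#' persists or logs data.  Only the executor holds the private key; it
#' decrypts, re-authenticates against a pluggable authenticator on every
#' single request, and only then spawns the command, tagged with the
#' verified identity.  A `key_id` (digest of the public key) travels in
#' every envelope so key rotation cleanly invalidates old envelopes.
#'
#' @name impersonation
NULL

#' Generate the executor key pair
#'
#' @param bits RSA modulus size; 2048 by default.
#' @return list with `public` and `private` openssl keys and `key_id`
#'   (SHA-256 of the DER-encoded public key).
#' @export
impersonation_keypair <- function(bits = 2048) {
  key <- openssl::rsa_keygen(bits)
  pub <- key$pubkey
  list(public = pub, private = key,
       key_id = sha256_hex(paste(as.character(openssl::write_der(pub)), collapse = "")))
}

#' Seal credentials into an envelope
#'
#' Encrypts `user:password` with the executor's public key and wraps the
#' ciphertext in transport-safe base64.  The plaintext never leaves this
#' function.
#'
#' @param user,password credentials.
#' @param public_key the executor's public key.
#' @param key_id the pair's key id.
#' @return a `credential_envelope` (ciphertext + encoding + key id).
#' @export
seal_credentials <- function(user, password, public_key, key_id) {
  if (grepl(":", user, fixed = TRUE)) abort("user name may not contain ':'")
  ct <- openssl::rsa_encrypt(charToRaw(paste0(user, ":", password)), public_key)
  structure(
    list(ciphertext_b64 = openssl::base64_encode(ct),
         encoding = "base64", key_id = key_id),
    class = "credential_envelope"
  )
}

#' @export
print.credential_envelope <- function(x, ...) {
  cat(sprintf("<credential_envelope> key %s.., %d base64 chars\n",
              substr(x$key_id, 1, 8), nchar(x$ciphertext_b64)))
  invisible(x)
}

#' In-memory authenticator (pluggable port)
#'
#' The executor is agnostic to the real authentication system behind it
#' (OS accounts, LDAP, PAM ...); that claim is realized as an interface
#' with a `verify(user, password)` method.  This implementation backs it
#' with an in-memory user table storing salted password hashes, counts
#' every verification (so tests can prove each execution re-authenticates)
#' and supports deactivating accounts.
#'
#' @param users named list/vector: user -> password (hashed on ingestion).
#' @return a `MemoryAuthenticator` R6 object.
#' @export
memory_authenticator <- function(users = list()) {
  a <- MemoryAuthenticator$new()
  for (u in names(users)) a$add_user(u, users[[u]])
  a
}

#' @rdname memory_authenticator
#' @export
MemoryAuthenticator <- R6::R6Class("MemoryAuthenticator",
  public = list(
    #' @field verify_count number of verification attempts so far.
    verify_count = 0L,

    #' @description Create an empty user table.
    initialize = function() {
      private$users <- new.env(parent = emptyenv())
    },

    #' @description Add (or replace) a user; the password is stored as a
    #'   salted SHA-256 hash, never in plaintext.
    #' @param user,password credentials.
    add_user = function(user, password) {
      salt <- paste(sample(c(letters, 0:9), 16, replace = TRUE), collapse = "")
      assign(user, list(salt = salt, hash = sha256_hex(paste0(salt, password)),
                        active = TRUE),
             envir = private$users)
      invisible(user)
    },

    #' @description Deactivate an account; verification then always fails.
    #' @param user user name.
    deactivate = function(user) {
      if (exists(user, envir = private$users)) {
        u <- get(user, envir = private$users)
        u$active <- FALSE
        assign(user, u, envir = private$users)
      }
      invisible(user)
    },

    #' @description Verify credentials.
    #' @param user,password credentials.
    verify = function(user, password) {
      self$verify_count <- self$verify_count + 1L
      if (!exists(user, envir = private$users)) return(FALSE)
      u <- get(user, envir = private$users)
      isTRUE(u$active) && identical(u$hash, sha256_hex(paste0(u$salt, password)))
    }
  ),
  private = list(users = NULL)
)

#' The impersonation executor
#'
#' Holds the private key and the authenticator.  `login()` seals and
#' verifies credentials, persisting the envelope (ciphertext only) and
#' issuing a session on success; `execute_as()` decrypts an envelope,
#' re-authenticates — valid credentials must accompany every request,
#' session or not — and only then spawns the command as a subprocess,
#' returning its streams, exit status and the verified identity tag.
#'
#' @param authenticator a [memory_authenticator()] (or any object with a
#'   `verify(user, password)` method).
#' @param keypair an [impersonation_keypair()]; generated if missing.
#' @param store_dir directory where envelopes are persisted.
#' @return an `Impersonator` R6 object.
#' @examples
#' \dontrun{
#' auth <- memory_authenticator(list(ann = "s3cret"))
#' ex <- impersonator(auth)
#' s <- ex$login("ann", "s3cret")
#' ex$execute_as(s$envelope, "echo ok")
#' }
#' @export
impersonator <- function(authenticator, keypair = impersonation_keypair(),
                         store_dir = tempfile("stageflow-envelopes")) {
  Impersonator$new(authenticator, keypair, store_dir)
}

#' @rdname impersonator
#' @export
Impersonator <- R6::R6Class("Impersonator",
  public = list(
    #' @field public_key the executor's public key (shareable).
    public_key = NULL,
    #' @field key_id id of the active key pair.
    key_id = NULL,
    #' @field store_dir where envelopes are persisted (ciphertext only).
    store_dir = NULL,
    #' @field log_lines audit log (never contains plaintext credentials).
    log_lines = character(),

    #' @description Create an executor.
    #' @param authenticator,keypair,store_dir see [impersonator()].
    initialize = function(authenticator, keypair, store_dir) {
      private$auth <- authenticator
      private$private_key <- keypair$private
      self$public_key <- keypair$public
      self$key_id <- keypair$key_id
      self$store_dir <- store_dir
      dir.create(store_dir, recursive = TRUE, showWarnings = FALSE)
    },

    #' @description Authenticate and store the sealed credentials.  On
    #'   verification failure nothing is stored.
    #' @param user,password credentials (sealed immediately; the
    #'   persisted artifacts only ever hold ciphertext).
    login = function(user, password) {
      envelope <- seal_credentials(user, password, self$public_key, self$key_id)
      creds <- private$open_envelope(envelope)
      if (is.null(creds) || !private$auth$verify(creds$user, creds$password)) {
        private$log(sprintf("login failed for user=%s", user))
        abort(sprintf("authentication failed for user '%s'", user))
      }
      session <- sf_next_id("session")
      writeLines(jsonlite::toJSON(unclass(envelope), auto_unbox = TRUE),
                 file.path(self$store_dir, paste0(user, ".envelope.json")))
      private$log(sprintf("login ok user=%s session=%s", user, session))
      list(session = session, envelope = envelope)
    },

    #' @description Stored envelope for a user (ciphertext form).
    #' @param user user name.
    stored_envelope = function(user) {
      p <- file.path(self$store_dir, paste0(user, ".envelope.json"))
      if (!file.exists(p)) abort(sprintf("no stored envelope for '%s'", user))
      raw <- jsonlite::fromJSON(read_text(p), simplifyVector = TRUE)
      structure(raw, class = "credential_envelope")
    },

    #' @description Decrypt, re-authenticate and run a command as the
    #'   envelope's user.  A stale or tampered envelope, a wrong password
    #'   or a deactivated account all fail before any process is spawned.
    #' @param envelope a `credential_envelope`.
    #' @param command shell command to run.
    #' @param wd working directory for the command.
    execute_as = function(envelope, command, wd = ".") {
      creds <- private$open_envelope(envelope)
      if (is.null(creds)) {
        private$log("execute rejected: envelope did not decrypt")
        abort("invalid credential envelope", class = "auth_failure")
      }
      if (!private$auth$verify(creds$user, creds$password)) {
        private$log(sprintf("execute rejected: re-authentication failed user=%s",
                            creds$user))
        abort(sprintf("re-authentication failed for user '%s'", creds$user),
              class = "auth_failure")
      }
      p <- processx::run("sh", c("-c", command), wd = wd, error_on_status = FALSE)
      private$log(sprintf("executed as user=%s exit=%d", creds$user, p$status))
      list(stdout = p$stdout, stderr = p$stderr,
           exit_status = p$status, identity = creds$user)
    }
  ),

  private = list(
    auth = NULL,
    private_key = NULL,

    # byte-level parse: a tampered ciphertext can decrypt to arbitrary
    # bytes, which must be rejected, never interpreted
    open_envelope = function(envelope) {
      if (!identical(envelope$key_id, self$key_id)) return(NULL)
      bytes <- tryCatch(
        openssl::rsa_decrypt(openssl::base64_decode(envelope$ciphertext_b64),
                             private$private_key),
        error = function(e) NULL)
      if (is.null(bytes)) return(NULL)
      idx <- which(bytes == charToRaw(":"))[1]
      if (is.na(idx)) return(NULL)
      user <- tryCatch(rawToChar(bytes[seq_len(idx - 1)]), error = function(e) NULL)
      pass <- tryCatch(rawToChar(bytes[-seq_len(idx)]), error = function(e) NULL)
      if (is.null(user) || is.null(pass) ||
          !all(validUTF8(c(user, pass))) || !nzchar(user)) {
        return(NULL)
      }
      list(user = user, password = pass)
    },

    log = function(line) {
      self$log_lines <- c(self$log_lines,
                          paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), line))
    }
  )
)

#' Serialize / parse an executor request
#'
#' The executor's wire protocol when deployed as a separate loopback
#' service: a plain-text JSON request carrying the base64-wrapped
#' envelope and the command, and a JSON response with streams and exit
#' status.  The in-process deployment used here speaks the same shapes.
#'
#' @param envelope a `credential_envelope`.
#' @param command command string.
#' @return `encode_executor_request()` returns JSON text;
#'   `decode_executor_request()` returns `list(envelope, command)`.
#' @export
encode_executor_request <- function(envelope, command) {
  jsonlite::toJSON(list(envelope = unclass(envelope), command = command),
                   auto_unbox = TRUE)
}

#' @rdname encode_executor_request
#' @param json request text.
#' @export
decode_executor_request <- function(json) {
  req <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  list(envelope = structure(as.list(req$envelope), class = "credential_envelope"),
       command = req$command)
}
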